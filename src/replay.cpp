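#include <Rcpp.h>
using namespace Rcpp;

// Sequential replay of a Rescorla-Wagner learner over one participant-session.
//
// stim:   0-based stimulus index (0..K-1)
// choice: 0 = left, 1 = right
// reward: 0 = negative feedback, 1 = positive feedback
// alpha:  K x 2 matrix of learning rates; column 0 applies to negative
//         feedback, column 1 to positive feedback
// beta:   softmax inverse temperature
// q_init: initial action value for every (stimulus, action)
//
// Returns the negative sum of log choice probabilities and, when traj is
// true, per-trial action values (before update), signed PE, and the modelled
// probability of the observed choice. The softmax is computed through the
// logistic of beta * (Q_chosen - Q_other), which is stable for beta up to the
// fitting bound of 50 with Q in [0, 1].
// [[Rcpp::export]]
List rw_replay_cpp(IntegerVector stim, IntegerVector choice,
                   IntegerVector reward, NumericMatrix alpha,
                   double beta, double q_init, bool traj) {
  const int n = stim.size();
  const int K = alpha.nrow();
  NumericMatrix Q(K, 2);
  std::fill(Q.begin(), Q.end(), q_init);

  NumericVector q_ch, q_un, delta, pch;
  if (traj) {
    q_ch = NumericVector(n);
    q_un = NumericVector(n);
    delta = NumericVector(n);
    pch = NumericVector(n);
  }

  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    const int s = stim[t];
    const int a = choice[t];
    const double qc = Q(s, a);
    const double qo = Q(s, 1 - a);
    const double p = 1.0 / (1.0 + std::exp(-beta * (qc - qo)));
    nll -= std::log(p);
    const double d = reward[t] - qc;
    if (traj) {
      q_ch[t] = qc;
      q_un[t] = qo;
      delta[t] = d;
      pch[t] = p;
    }
    Q(s, a) = qc + alpha(s, reward[t]) * d;
  }

  if (traj)
    return List::create(_["nll"] = nll, _["q_chosen"] = q_ch,
                        _["q_unchosen"] = q_un, _["delta"] = delta,
                        _["p_choice"] = pch);
  return List::create(_["nll"] = nll);
}
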