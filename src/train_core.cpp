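#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Piecewise-saturating output nonlinearity: k1*tanh(r) for r > 0,
// k2*tanh(r) for r <= 0 (tanh(0) = 0, so the split point is immaterial).
static inline double sigmoid_out(double r, double k1, double k2) {
  return (r > 0.0) ? k1 * std::tanh(r) : k2 * std::tanh(r);
}

// Inner training loop for the (N)BCM network.
//
// W        J x D weight matrix (modified copy returned)
// theta    length-J modification thresholds
// patches  N x D matrix of standardized input patches (rows are stimuli)
// schedule 0-based row indices into `patches`, one per iteration
// mode     0 = bcm, 1 = nbcm (divisive normalization before the updates)
// norm_drives_threshold  in nbcm mode, feed the normalized response to the
//          threshold update as well as the weight update (default contract)
// freeze_weights  run the threshold dynamics only (theta-tracking analyses)
// start_iteration global iteration count already consumed (resume support);
//          the annealing schedule depends on the global count, not the chunk
// record_every    if > 0, snapshot theta / eta / mean |W| at that stride
//
// [[Rcpp::export(name = ".train_core")]]
List train_core(arma::mat W,
                arma::vec theta,
                const arma::mat& patches,
                const arma::uvec& schedule,
                double k1,
                double k2,
                bool linear_output,
                double tau,
                double eta0,
                double anneal_factor,
                int mode,
                double alpha,
                double beta,
                bool norm_drives_threshold,
                bool freeze_weights,
                double start_iteration,
                int record_every) {
  const arma::uword J = W.n_rows;
  const arma::uword n_steps = schedule.n_elem;

  std::vector<double> rec_it, rec_eta, rec_mean_abs_w;
  std::vector<arma::vec> rec_theta;

  double eta = eta0 * std::pow(anneal_factor,
                               std::floor(start_iteration / 1000.0));
  bool diverged = false;
  arma::uword t = 0;

  arma::vec r(J), c(J), c_learn(J), c_thr(J);

  for (t = 0; t < n_steps; ++t) {
    const double global_it = start_iteration + static_cast<double>(t);
    // stepwise annealing: eta drops by (1 - anneal_factor) once per 1000
    // global iterations
    eta = eta0 * std::pow(anneal_factor, std::floor(global_it / 1000.0));

    const arma::rowvec d = patches.row(schedule[t]);
    r = W * d.t();
    if (linear_output) {
      c = r;
    } else {
      for (arma::uword j = 0; j < J; ++j) c[j] = sigmoid_out(r[j], k1, k2);
    }

    if (mode == 1) {
      const double pool = alpha + arma::dot(c, c);
      c_learn = (beta / pool) * c;
      c_thr = norm_drives_threshold ? c_learn : c;
    } else {
      c_learn = c;
      c_thr = c;
    }

    if (!freeze_weights) {
      // delta m_ij = eta * c_j * (c_j - theta_j) * d_i
      W += eta * ((c_learn % (c_learn - theta)) * d);
    }
    // delta theta_j = (c_j^2 - theta_j) / tau
    theta += (arma::square(c_thr) - theta) / tau;

    if (record_every > 0 && ((t + 1) % record_every == 0)) {
      rec_it.push_back(global_it + 1.0);
      rec_eta.push_back(eta);
      rec_mean_abs_w.push_back(arma::mean(arma::mean(arma::abs(W))));
      rec_theta.push_back(theta);
    }

    if ((t + 1) % 1000 == 0 || t + 1 == n_steps) {
      if (!W.is_finite() || !theta.is_finite()) {
        diverged = true;
        ++t;
        break;
      }
    }
  }

  arma::mat theta_trace;
  if (!rec_theta.empty()) {
    theta_trace.set_size(J, rec_theta.size());
    for (size_t k = 0; k < rec_theta.size(); ++k)
      theta_trace.col(k) = rec_theta[k];
  }

  return List::create(
      _["weights"] = W,
      _["thresholds"] = theta,
      _["eta"] = eta,
      _["iterations_run"] = static_cast<double>(t),
      _["diverged"] = diverged,
      _["trace"] = List::create(_["iteration"] = rec_it,
                                _["eta"] = rec_eta,
                                _["mean_abs_weight"] = rec_mean_abs_w,
                                _["thresholds"] = theta_trace));
}
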