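#include <Rcpp.h>
using namespace Rcpp;

// Continuous-time Markov simulation (Gillespie direct method) of ribosome
// traffic along an ORF: extended particles of `footprint` codons tracked by
// their A-site position (5' edge of the occupied stretch).
//
//  - initiation: A-site placed at codon 1 with rate alpha_on iff codons
//    1..footprint carry no part of a ribosome (first A-site > footprint);
//  - elongation: A-site i -> i+1 with rate omega[i+1] iff the ribosome ahead
//    has its A-site at >= i + 1 + footprint;
//  - drop-off: any ribosome detaches with rate gamma;
//  - termination: the ribosome with A-site at codon L leaves with rate
//    alpha_off.
//
// Occupancy is time-averaged after burn_in over `sample_time`, split into
// n_batches batches for batch-means standard errors. Uses R's RNG so runs
// are reproducible under set.seed().
//
// [[Rcpp::export]]
List gillespie_tasep(NumericVector omega, double alpha_on, double alpha_off,
                     double gamma, int footprint, double burn_in,
                     double sample_time, int n_batches, bool check_exclusion) {
  const int L = omega.size();
  if (L < footprint) stop("ORF shorter than the ribosome footprint");
  if (n_batches < 2) stop("need at least 2 batches");

  std::vector<int> pos;  // ascending A-site positions; back() is downstream-most
  pos.reserve(L / footprint + 2);

  const double t_end = burn_in + sample_time;
  const double batch_len = sample_time / n_batches;

  NumericMatrix batch_rhoA(n_batches, L);
  NumericMatrix batch_cov(n_batches, L);
  NumericVector batch_term(n_batches);
  double t = 0.0;
  long long n_events = 0;

  std::vector<double> rate;  // 0 = initiation, then per-ribosome (hop|term), then gamma each
  std::vector<int> what;     // 0 init, 1 advance ribosome k, 2 drop ribosome k
  std::vector<int> who;

  RNGScope scope;

  while (t < t_end) {
    // build rates
    rate.clear(); what.clear(); who.clear();
    double total = 0.0;
    bool entry_clear = pos.empty() || pos.front() > footprint;
    if (alpha_on > 0 && entry_clear) {
      rate.push_back(alpha_on); what.push_back(0); who.push_back(-1);
      total += alpha_on;
    }
    const int n = (int)pos.size();
    for (int k = 0; k < n; ++k) {
      int p = pos[k];
      if (p == L) {
        rate.push_back(alpha_off); what.push_back(1); who.push_back(k);
        total += alpha_off;
      } else {
        bool clear_ahead = (k == n - 1) || (pos[k + 1] >= p + 1 + footprint);
        if (clear_ahead) {
          double w = omega[p];  // omega[p] is the rate of codon p+1 (0-based vector)
          rate.push_back(w); what.push_back(1); who.push_back(k);
          total += w;
        }
      }
      if (gamma > 0) {
        rate.push_back(gamma); what.push_back(2); who.push_back(k);
        total += gamma;
      }
    }

    if (total <= 0.0) {
      // absorbing empty lattice (alpha_on == 0): occupancy stays zero
      t = t_end;
      break;
    }

    double dt = -std::log(unif_rand()) / total;
    double t_next = t + dt;

    // accumulate time-weighted occupancy over [t, min(t_next, t_end)),
    // split across batch boundaries
    double a = std::max(t, burn_in);
    double b = std::min(t_next, t_end);
    if (b > a && !pos.empty()) {
      double cursor = a;
      while (cursor < b) {
        int bi = (int)std::floor((cursor - burn_in) / batch_len);
        if (bi >= n_batches) bi = n_batches - 1;
        double edge = burn_in + (bi + 1) * batch_len;
        double seg = std::min(b, edge) - cursor;
        for (size_t k = 0; k < pos.size(); ++k) {
          int p = pos[k];
          batch_rhoA(bi, p - 1) += seg;
          int hi = std::min(p + footprint - 1, L);
          for (int q = p; q <= hi; ++q) batch_cov(bi, q - 1) += seg;
        }
        cursor += seg;
        if (seg <= 0) break;  // guard against FP stall
      }
    }

    if (t_next >= t_end) { t = t_end; break; }
    t = t_next;

    // pick event
    double r = unif_rand() * total;
    size_t e = 0;
    double acc = 0.0;
    for (; e < rate.size(); ++e) {
      acc += rate[e];
      if (r <= acc) break;
    }
    if (e >= rate.size()) e = rate.size() - 1;

    if (what[e] == 0) {
      pos.insert(pos.begin(), 1);
    } else if (what[e] == 1) {
      int k = who[e];
      if (pos[k] == L) {
        pos.erase(pos.begin() + k);
        if (t >= burn_in) {
          int bi = (int)std::floor((t - burn_in) / batch_len);
          if (bi >= n_batches) bi = n_batches - 1;
          batch_term[bi] += 1.0;
        }
      } else {
        pos[k] += 1;
      }
    } else {
      pos.erase(pos.begin() + who[e]);
    }

    if (check_exclusion) {
      for (size_t k = 1; k < pos.size(); ++k) {
        if (pos[k] - pos[k - 1] < footprint)
          stop("exclusion violated at event %d", (int)n_events);
      }
    }
    ++n_events;
  }

  // batch means -> estimates and standard errors
  NumericVector rho(L), rho_se(L), cov(L), cov_se(L);
  for (int i = 0; i < L; ++i) {
    double m = 0, m2 = 0, c = 0, c2 = 0;
    for (int bI = 0; bI < n_batches; ++bI) {
      double x = batch_rhoA(bI, i) / batch_len;
      double y = batch_cov(bI, i) / batch_len;
      m += x; m2 += x * x; c += y; c2 += y * y;
    }
    m /= n_batches; c /= n_batches;
    double vx = (m2 / n_batches - m * m) * n_batches / (n_batches - 1.0);
    double vy = (c2 / n_batches - c * c) * n_batches / (n_batches - 1.0);
    rho[i] = m; cov[i] = c;
    rho_se[i] = std::sqrt(std::max(vx, 0.0) / n_batches);
    cov_se[i] = std::sqrt(std::max(vy, 0.0) / n_batches);
  }
  double jm = 0, j2 = 0;
  for (int bI = 0; bI < n_batches; ++bI) {
    double x = batch_term[bI] / batch_len;
    jm += x; j2 += x * x;
  }
  jm /= n_batches;
  double vj = (j2 / n_batches - jm * jm) * n_batches / (n_batches - 1.0);

  return List::create(
      _["rho"] = rho, _["rho_se"] = rho_se, _["coverage"] = cov,
      _["coverage_se"] = cov_se, _["flux"] = jm,
      _["flux_se"] = std::sqrt(std::max(vj, 0.0) / n_batches),
      _["n_events"] = (double)n_events);
}
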