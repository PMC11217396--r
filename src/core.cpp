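// Compiled core: GA loop over layered linear networks, the nonlinear
// (tanh) classification GA, and the fixed-step RK4 integrator for the
// multiplicative gradient flow.  All randomness is drawn from R's RNG so
// set.seed() gives bit-reproducible runs.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double frob2(const arma::mat& X) {
  return arma::accu(arma::square(X));
}

// A = A^(L) ... A^(1); slice l-1 holds A^(l)
static arma::mat compose_cube(const arma::cube& A) {
  arma::mat P = A.slice(0);
  for (arma::uword l = 1; l < A.n_slices; ++l) P = A.slice(l) * P;
  return P;
}

// F = -||A - G||_F^2 minus optional L1/L2 link cost (reg 0/1/2)
static double eval_fitness(const arma::cube& A, const arma::mat& G,
                           int reg, double lambda) {
  double F = -frob2(compose_cube(A) - G);
  if (reg == 1) {
    double s = 0;
    for (arma::uword l = 0; l < A.n_slices; ++l) s += arma::accu(arma::abs(A.slice(l)));
    F -= lambda * s;
  } else if (reg == 2) {
    double s = 0;
    for (arma::uword l = 0; l < A.n_slices; ++l) s += arma::accu(arma::square(A.slice(l)));
    F -= lambda * s;
  }
  return F;
}

// Node-importance profile P_i^l for middle node layers 2..L.
// Row j of the result corresponds to node layer j+2.
// def 1: squared fitness drop by deletion; def 2: squared Frobenius norm of
// the in-out change; def 3: maximal link intensity touching the node.
static arma::mat importance_cube(const arma::cube& A, const arma::mat& G, int def) {
  const int M = A.n_rows, L = A.n_slices;
  arma::mat P(L - 1, M, arma::fill::zeros);
  arma::mat full = compose_cube(A);
  double F_full = -frob2(full - G);
  for (int j = 0; j < L - 1; ++j) {
    arma::rowvec raw(M);
    for (int i = 0; i < M; ++i) {
      if (def == 3) {
        double m_in = A.slice(j).row(i).max();
        double m_out = A.slice(j + 1).col(i).max();
        raw(i) = std::max(m_in, m_out);
      } else {
        arma::cube B = A;
        B.slice(j).row(i).zeros();
        B.slice(j + 1).col(i).zeros();
        if (def == 1) {
          // ratio of raw fitness drops: P_i = |dF_i| / sum_j |dF_j|
          raw(i) = std::abs(-frob2(compose_cube(B) - G) - F_full);
        } else {
          raw(i) = frob2(full - compose_cube(B));
        }
      }
    }
    double s = arma::accu(raw);
    if (s > 0) P.row(j) = raw / s;
  }
  return P;
}

static void waist_from_profile(const arma::mat& P, double thr,
                               arma::irowvec& counts, int& waist) {
  const int Lm = P.n_rows, M = P.n_cols;
  counts.set_size(Lm);
  waist = M + 1;
  for (int j = 0; j < Lm; ++j) {
    int c = 0;
    for (int i = 0; i < M; ++i) if (P(j, i) > thr) ++c;
    counts(j) = c;
    if (c < waist) waist = c;
  }
}

// sample k distinct indices from 0..n-1 (partial Fisher-Yates, R RNG)
static void sample_distinct(int n, int k, std::vector<int>& scratch,
                            std::vector<int>& out) {
  scratch.resize(n);
  for (int i = 0; i < n; ++i) scratch[i] = i;
  out.resize(k);
  for (int t = 0; t < k; ++t) {
    int j = t + (int)(unif_rand() * (n - t));
    if (j >= n) j = n - 1;
    std::swap(scratch[t], scratch[j]);
    out[t] = scratch[t];
  }
}

static double draw_xi(double mean, double sd, bool positive) {
  double xi = mean + sd * norm_rand();
  if (positive) while (xi <= 0) xi = mean + sd * norm_rand();
  return xi;
}

// [[Rcpp::export]]
List cpp_evolve(List init_pop, IntegerVector goal_gens, List goal_list,
                int mutate_count, double xi_mean, double xi_sd, bool xi_positive,
                int selection, int tour_size, double conv_fitness,
                int max_generations, int reg, double reg_lambda,
                int record_stride, int active_def, double active_threshold,
                bool mutate_copies_only, bool stop_at_convergence,
                double pad_scale) {
  const int N = init_pop.size();
  std::vector<arma::cube> pop(N);
  for (int i = 0; i < N; ++i) {
    NumericVector a = init_pop[i];
    IntegerVector d = a.attr("dim");
    pop[i] = arma::cube(a.begin(), d[0], d[1], d[2]);
  }
  int M = pop[0].n_rows;
  const int L = pop[0].n_slices;
  const int n_goal = goal_list.size();

  arma::mat G;
  int goal_idx = -1;
  std::vector<arma::cube> pool(2 * N);
  std::vector<double> fitpop(N), fitpool(2 * N);
  std::vector<int> scratch, chosen, newidx;
  int converged_at = -1;
  bool fit_valid = false;

  const int ncol = 5 + (L - 1); // gen, mean, best, counts.., waist, epoch
  std::vector<double> rec;
  rec.reserve(1024);

  auto best_index = [&](void) {
    int b = 0;
    for (int i = 1; i < N; ++i) if (fitpop[i] > fitpop[b]) b = i;
    return b;
  };
  auto record_row = [&](int gen) {
    int b = best_index();
    double mean = 0, best = fitpop[b];
    for (int i = 0; i < N; ++i) mean += fitpop[i];
    mean /= N;
    arma::mat P = importance_cube(pop[b], G, active_def);
    arma::irowvec counts;
    int waist;
    waist_from_profile(P, active_threshold, counts, waist);
    rec.push_back((double)gen);
    rec.push_back(mean);
    rec.push_back(best);
    for (int j = 0; j < L - 1; ++j) rec.push_back((double)counts(j));
    rec.push_back((double)waist);
    rec.push_back((double)goal_idx);
  };

  int last_recorded = -1;
  int final_gen = 0;
  std::string status = "max_generations";

  for (int gen = 0; gen <= max_generations; ++gen) {
    // scheduled goal switches become active at this generation
    while (goal_idx + 1 < n_goal && goal_gens[goal_idx + 1] <= gen) {
      ++goal_idx;
      arma::mat Gn = as<arma::mat>(goal_list[goal_idx]);
      if ((int)Gn.n_rows > M) { // network padding on goal expansion
        int Mn = Gn.n_rows;
        for (int i = 0; i < N; ++i) {
          arma::cube c(Mn, Mn, L);
          for (int l = 0; l < L; ++l) {
            arma::mat S(Mn, Mn);
            for (int a = 0; a < Mn; ++a)
              for (int b2 = 0; b2 < Mn; ++b2)
                S(a, b2) = (a < M && b2 < M) ? pop[i].slice(l)(a, b2)
                                             : unif_rand() * pad_scale;
            c.slice(l) = S;
          }
          pop[i] = c;
        }
        M = Mn;
      }
      G = Gn;
      fit_valid = false;
    }
    if (!fit_valid) {
      for (int i = 0; i < N; ++i) fitpop[i] = eval_fitness(pop[i], G, reg, reg_lambda);
      fit_valid = true;
    }
    if (gen == 0) {
      record_row(0);
      last_recorded = 0;
      double mean0 = 0;
      for (int i = 0; i < N; ++i) mean0 += fitpop[i];
      mean0 /= N;
      if (mean0 >= conv_fitness) {
        converged_at = 0;
        if (stop_at_convergence) { status = "converged"; break; }
      }
      continue;
    }

    // duplicate to 2N (parents first, copies after)
    for (int i = 0; i < N; ++i) {
      pool[i] = pop[i];
      pool[N + i] = pop[i];
      fitpool[i] = fitpop[i];
      fitpool[N + i] = fitpop[i];
    }
    // one single-link mutation in each of mutate_count distinct individuals
    if (mutate_copies_only) {
      sample_distinct(N, std::min(mutate_count, N), scratch, chosen);
      for (size_t t = 0; t < chosen.size(); ++t) chosen[t] += N;
    } else {
      sample_distinct(2 * N, std::min(mutate_count, 2 * N), scratch, chosen);
    }
    for (size_t t = 0; t < chosen.size(); ++t) {
      int idx = chosen[t];
      int l = (int)(unif_rand() * L); if (l >= L) l = L - 1;
      int i = (int)(unif_rand() * M); if (i >= M) i = M - 1;
      int j = (int)(unif_rand() * M); if (j >= M) j = M - 1;
      pool[idx].slice(l)(i, j) *= draw_xi(xi_mean, xi_sd, xi_positive);
      fitpool[idx] = eval_fitness(pool[idx], G, reg, reg_lambda);
    }
    // selection of N from 2N
    newidx.resize(N);
    if (selection == 1) { // elite
      std::vector<int> ord(2 * N);
      for (int i = 0; i < 2 * N; ++i) ord[i] = i;
      std::stable_sort(ord.begin(), ord.end(),
                       [&](int a, int b) { return fitpool[a] > fitpool[b]; });
      for (int i = 0; i < N; ++i) newidx[i] = ord[i];
    } else { // tournament: group sampled without replacement, winner advances
      std::vector<int> grp;
      int gs = std::min(tour_size, 2 * N);
      for (int s = 0; s < N; ++s) {
        sample_distinct(2 * N, gs, scratch, grp);
        int w = grp[0];
        for (int t = 1; t < gs; ++t) if (fitpool[grp[t]] > fitpool[w]) w = grp[t];
        newidx[s] = w;
      }
    }
    std::vector<arma::cube> nextpop(N);
    for (int i = 0; i < N; ++i) {
      nextpop[i] = pool[newidx[i]];
      fitpop[i] = fitpool[newidx[i]];
    }
    pop.swap(nextpop);
    final_gen = gen;

    double mean = 0;
    for (int i = 0; i < N; ++i) mean += fitpop[i];
    mean /= N;
    bool conv_now = (mean >= conv_fitness);
    if (conv_now && converged_at < 0) converged_at = gen;
    bool stop = (conv_now && stop_at_convergence) || gen == max_generations;
    if (gen % record_stride == 0 || stop) { record_row(gen); last_recorded = gen; }
    if (conv_now && stop_at_convergence) { status = "converged"; break; }
  }
  if (last_recorded != final_gen && final_gen > 0) record_row(final_gen);

  int b = best_index();
  NumericVector bestA(M * M * L);
  std::copy(pop[b].begin(), pop[b].end(), bestA.begin());
  bestA.attr("dim") = IntegerVector::create(M, M, L);

  int nrow = rec.size() / ncol;
  NumericMatrix records(nrow, ncol);
  for (int r = 0; r < nrow; ++r)
    for (int c2 = 0; c2 < ncol; ++c2) records(r, c2) = rec[r * ncol + c2];

  return List::create(_["records"] = records,
                      _["best"] = bestA,
                      _["best_fitness"] = fitpop[b],
                      _["converged_at"] = converged_at,
                      _["M"] = M,
                      _["status"] = status);
}

// ---------------------------------------------------------------------------
// Nonlinear (tanh) classification variant: u = f(A4 f(A3 f(A2 f(A1 v)))),
// f(x) = (1 + tanh(x))/2; A1 is 6 x 64, A2..A4 are 6 x 6.

static arma::mat nl_forward_all(const std::vector<arma::mat>& A, const arma::mat& V) {
  arma::mat U = V;
  for (size_t l = 0; l < A.size(); ++l)
    U = (1.0 + arma::tanh(A[l] * U)) / 2.0;
  return U;
}

static double nl_fitness(const std::vector<arma::mat>& A, const arma::mat& V,
                         const arma::mat& T) {
  return -arma::accu(arma::square(nl_forward_all(A, V) - T));
}

// importance by squared deletion fitness drop for middle node layers 2..4
static arma::mat nl_importance(const std::vector<arma::mat>& A, const arma::mat& V,
                               const arma::mat& T) {
  const int Lm = A.size() - 1; // middle node layers
  const int Mm = A[1].n_rows;
  arma::mat P(Lm, Mm, arma::fill::zeros);
  double F_full = nl_fitness(A, V, T);
  for (int j = 0; j < Lm; ++j) {
    arma::rowvec raw(Mm);
    for (int i = 0; i < Mm; ++i) {
      std::vector<arma::mat> B = A;
      B[j].row(i).zeros();
      B[j + 1].col(i).zeros();
      raw(i) = std::abs(nl_fitness(B, V, T) - F_full);
    }
    double s = arma::accu(raw);
    if (s > 0) P.row(j) = raw / s;
  }
  return P;
}

// [[Rcpp::export]]
List cpp_evolve_nl(List init_pop, NumericMatrix images, NumericMatrix targets,
                   int mutate_count, double xi_mean, double xi_sd,
                   int selection, int tour_size, double conv_fitness,
                   int max_generations, int record_stride,
                   double active_threshold, bool stop_at_convergence) {
  const int N = init_pop.size();
  std::vector<std::vector<arma::mat>> pop(N);
  for (int i = 0; i < N; ++i) {
    List ind = init_pop[i];
    std::vector<arma::mat> A(ind.size());
    for (int l = 0; l < (int)ind.size(); ++l) A[l] = as<arma::mat>(ind[l]);
    pop[i] = A;
  }
  const int nlayer = pop[0].size();
  arma::mat V = as<arma::mat>(images);   // 64 x n
  arma::mat T = as<arma::mat>(targets);  // 6 x n
  // entry counts per layer for uniform-entry mutation
  std::vector<int> cum(nlayer + 1, 0);
  for (int l = 0; l < nlayer; ++l)
    cum[l + 1] = cum[l] + pop[0][l].n_rows * pop[0][l].n_cols;
  const int total_entries = cum[nlayer];

  std::vector<std::vector<arma::mat>> pool(2 * N);
  std::vector<double> fitpop(N), fitpool(2 * N);
  std::vector<int> scratch, chosen, newidx;
  for (int i = 0; i < N; ++i) fitpop[i] = nl_fitness(pop[i], V, T);
  int converged_at = -1;

  const int Lm = nlayer - 1;
  const int ncol = 5 + Lm;
  std::vector<double> rec;
  auto best_index = [&](void) {
    int b = 0;
    for (int i = 1; i < N; ++i) if (fitpop[i] > fitpop[b]) b = i;
    return b;
  };
  auto record_row = [&](int gen) {
    int b = best_index();
    double mean = 0;
    for (int i = 0; i < N; ++i) mean += fitpop[i];
    mean /= N;
    arma::mat P = nl_importance(pop[b], V, T);
    arma::irowvec counts;
    int waist;
    waist_from_profile(P, active_threshold, counts, waist);
    rec.push_back((double)gen);
    rec.push_back(mean);
    rec.push_back(fitpop[b]);
    for (int j = 0; j < Lm; ++j) rec.push_back((double)counts(j));
    rec.push_back((double)waist);
    rec.push_back(0.0);
  };
  record_row(0);
  int last_recorded = 0, final_gen = 0;
  std::string status = "max_generations";

  for (int gen = 1; gen <= max_generations; ++gen) {
    for (int i = 0; i < N; ++i) {
      pool[i] = pop[i];
      pool[N + i] = pop[i];
      fitpool[i] = fitpop[i];
      fitpool[N + i] = fitpop[i];
    }
    sample_distinct(2 * N, std::min(mutate_count, 2 * N), scratch, chosen);
    for (size_t t = 0; t < chosen.size(); ++t) {
      int idx = chosen[t];
      int e = (int)(unif_rand() * total_entries);
      if (e >= total_entries) e = total_entries - 1;
      int l = 0;
      while (e >= cum[l + 1]) ++l;
      int off = e - cum[l];
      int nr = pool[idx][l].n_rows;
      // xi ~ N(1, 0.5): sign flips permitted, no resampling
      pool[idx][l](off % nr, off / nr) *= xi_mean + xi_sd * norm_rand();
      fitpool[idx] = nl_fitness(pool[idx], V, T);
    }
    newidx.resize(N);
    if (selection == 1) {
      std::vector<int> ord(2 * N);
      for (int i = 0; i < 2 * N; ++i) ord[i] = i;
      std::stable_sort(ord.begin(), ord.end(),
                       [&](int a, int b) { return fitpool[a] > fitpool[b]; });
      for (int i = 0; i < N; ++i) newidx[i] = ord[i];
    } else {
      std::vector<int> grp;
      int gs = std::min(tour_size, 2 * N);
      for (int s = 0; s < N; ++s) {
        sample_distinct(2 * N, gs, scratch, grp);
        int w = grp[0];
        for (int t = 1; t < gs; ++t) if (fitpool[grp[t]] > fitpool[w]) w = grp[t];
        newidx[s] = w;
      }
    }
    std::vector<std::vector<arma::mat>> nextpop(N);
    for (int i = 0; i < N; ++i) {
      nextpop[i] = pool[newidx[i]];
      fitpop[i] = fitpool[newidx[i]];
    }
    pop.swap(nextpop);
    final_gen = gen;
    double mean = 0;
    for (int i = 0; i < N; ++i) mean += fitpop[i];
    mean /= N;
    bool conv_now = (mean >= conv_fitness);
    if (conv_now && converged_at < 0) converged_at = gen;
    bool stop = (conv_now && stop_at_convergence) || gen == max_generations;
    if (gen % record_stride == 0 || stop) { record_row(gen); last_recorded = gen; }
    if (conv_now && stop_at_convergence) { status = "converged"; break; }
  }
  if (last_recorded != final_gen && final_gen > 0) record_row(final_gen);

  int b = best_index();
  List bestA(nlayer);
  for (int l = 0; l < nlayer; ++l) bestA[l] = wrap(pop[b][l]);
  int nrow = rec.size() / ncol;
  NumericMatrix records(nrow, ncol);
  for (int r = 0; r < nrow; ++r)
    for (int c2 = 0; c2 < ncol; ++c2) records(r, c2) = rec[r * ncol + c2];
  return List::create(_["records"] = records, _["best"] = bestA,
                      _["best_fitness"] = fitpop[b],
                      _["converged_at"] = converged_at, _["status"] = status);
}

// ---------------------------------------------------------------------------
// Multiplicative gradient flow dA^(l)/dt = eta A^(l) o dF/dA^(l), RK4.

static arma::cube flow_deriv(const arma::cube& A, const arma::mat& G, double eta) {
  const int M = A.n_rows, L = A.n_slices;
  // prefix P[k] = A^(k) ... A^(1) (P[0] = I); suffix S[k] = A^(L) ... A^(k)
  std::vector<arma::mat> P(L + 1), S(L + 2);
  P[0] = arma::eye(M, M);
  for (int k = 1; k <= L; ++k) P[k] = A.slice(k - 1) * P[k - 1];
  S[L + 1] = arma::eye(M, M);
  for (int k = L; k >= 1; --k) S[k] = S[k + 1] * A.slice(k - 1);
  arma::mat E = P[L] - G;
  arma::cube D(M, M, L);
  for (int l = 1; l <= L; ++l)
    D.slice(l - 1) = (-2.0 * eta) * (S[l + 1].t() * E * P[l - 1].t()) % A.slice(l - 1);
  return D;
}

// [[Rcpp::export]]
List cpp_ode_rk4(NumericVector A_init, NumericMatrix goal, double eta,
                 double dt, double t_end, double entry_cap,
                 int record_stride, double conv_fitness,
                 bool stop_at_convergence, int active_def,
                 double active_threshold) {
  IntegerVector d = A_init.attr("dim");
  arma::cube A(A_init.begin(), d[0], d[1], d[2]);
  arma::mat G = as<arma::mat>(goal);
  const int L = A.n_slices;
  const int ncol = L + 2; // t, fitness, (L-1) counts, waist
  std::vector<double> rec;
  auto record_row = [&](double t) {
    arma::mat P = importance_cube(A, G, active_def);
    arma::irowvec counts;
    int waist;
    waist_from_profile(P, active_threshold, counts, waist);
    rec.push_back(t);
    rec.push_back(-frob2(compose_cube(A) - G));
    for (int j = 0; j < L - 1; ++j) rec.push_back((double)counts(j));
    rec.push_back((double)waist);
  };
  std::string status = "t_end";
  const long nsteps = (long)std::ceil(t_end / dt);
  double t = 0;
  record_row(0.0);
  long last_recorded = 0;
  for (long s = 1; s <= nsteps; ++s) {
    arma::cube k1 = flow_deriv(A, G, eta);
    arma::cube k2 = flow_deriv(A + (dt / 2) * k1, G, eta);
    arma::cube k3 = flow_deriv(A + (dt / 2) * k2, G, eta);
    arma::cube k4 = flow_deriv(A + dt * k3, G, eta);
    arma::cube Anew = A + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4);
    if (!Anew.is_finite()) { status = "nonfinite"; break; }
    A = Anew;
    t = s * dt;
    if (A.max() > entry_cap || A.min() < -entry_cap) {
      status = "diverged";
      record_row(t);
      last_recorded = s;
      break;
    }
    bool conv = false;
    if (stop_at_convergence && -frob2(compose_cube(A) - G) >= conv_fitness) {
      conv = true;
      status = "converged";
    }
    if (s % record_stride == 0 || s == nsteps || conv) { record_row(t); last_recorded = s; }
    if (conv) break;
  }
  NumericVector Afin(A.n_elem);
  std::copy(A.begin(), A.end(), Afin.begin());
  Afin.attr("dim") = IntegerVector::create(A.n_rows, A.n_cols, A.n_slices);
  int nrow = rec.size() / ncol;
  NumericMatrix records(nrow, ncol);
  for (int r = 0; r < nrow; ++r)
    for (int c2 = 0; c2 < ncol; ++c2) records(r, c2) = rec[r * ncol + c2];
  return List::create(_["records"] = records, _["final"] = Afin,
                      _["t"] = t, _["status"] = status);
}

// [[Rcpp::export]]
NumericMatrix cpp_importance(NumericVector A_arr, NumericMatrix goal, int def) {
  IntegerVector d = A_arr.attr("dim");
  arma::cube A(A_arr.begin(), d[0], d[1], d[2]);
  return wrap(importance_cube(A, as<arma::mat>(goal), def));
}
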