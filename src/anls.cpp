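#include <RcppArmadillo.h>
#include <map>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Multi-RHS non-negative least squares on the normal equations:
// minimise ||A Z - B||_F s.t. Z >= 0, given AtA = A'A and AtB = A'B.
// Block principal pivoting (Kim & Park), with the passive-set indicator F
// carried in/out so repeated calls with slowly-changing problems (the
// alternating iterations of ANLS) warm-start and usually settle in one
// pivot round. Columns sharing a passive set share one Cholesky; the small
// solves (q <= 16) run in stack buffers to avoid allocation churn.
#define BPP_MAXQ 16

static void nnls_bpp(const mat& AtA, const mat& AtB, mat& X, umat& F) {
  const int q = static_cast<int>(AtA.n_rows);
  const int r = static_cast<int>(AtB.n_cols);
  if (q > BPP_MAXQ) Rcpp::stop("nnls_bpp supports at most %d variables", BPP_MAXQ);
  X.set_size(q, r);
  // XY holds x on the passive set and the dual y on the active set
  // (disjoint index sets, so one buffer serves both)
  mat XY(q, r, fill::zeros);
  const double* a = AtA.memptr();
  const double* b = AtB.memptr();
  double* xy = XY.memptr();

  std::vector<signed char> alpha(r, 3);
  std::vector<int> beta(r, q + 1);
  std::vector<bool> done(r, false);
  const double tol = 1e-9 * std::max(1.0, abs(AtB).max());
  const int max_pivot = 3 * q + 30;
  const int nkeys = 1 << q;
  std::vector<int> head(nkeys, -1), nxt(r, -1);
  std::vector<int> keylist;
  keylist.reserve(256);

  for (int round = 0; round < max_pivot; ++round) {
    // bucket active columns by passive-set bitmask
    keylist.clear();
    bool any_active = false;
    for (int j = 0; j < r; ++j) {
      if (done[j]) continue;
      any_active = true;
      int key = 0;
      for (int i = 0; i < q; ++i) if (F(i, j)) key |= (1 << i);
      if (head[key] == -1) keylist.push_back(key);
      nxt[j] = head[key];
      head[key] = j;
    }
    if (!any_active) break;

    for (size_t kk = 0; kk < keylist.size(); ++kk) {
      const int key = keylist[kk];
      int Fi[BPP_MAXQ], Gi[BPP_MAXQ];
      int f = 0, gq = 0;
      for (int i = 0; i < q; ++i) {
        if (key & (1 << i)) Fi[f++] = i; else Gi[gq++] = i;
      }
      if (f == 0) {
        for (int j = head[key]; j != -1; j = nxt[j]) {
          for (int i = 0; i < q; ++i) xy[i + j * q] = -b[i + j * q];
        }
        head[key] = -1;
        continue;
      }
      // Cholesky of AtA[Fi, Fi] (lower) for this group's pattern
      double L[BPP_MAXQ * BPP_MAXQ];
      bool chol_ok = true;
      {
        double M[BPP_MAXQ][BPP_MAXQ];
        for (int c = 0; c < f; ++c)
          for (int rr = 0; rr < f; ++rr)
            M[rr][c] = a[Fi[rr] + Fi[c] * q];
        for (int c = 0; c < f && chol_ok; ++c) {
          double d = M[c][c];
          for (int k2 = 0; k2 < c; ++k2) d -= M[c][k2] * M[c][k2];
          if (d <= 0) { chol_ok = false; break; }
          M[c][c] = std::sqrt(d);
          for (int rr = c + 1; rr < f; ++rr) {
            double s = M[rr][c];
            for (int k2 = 0; k2 < c; ++k2) s -= M[rr][k2] * M[c][k2];
            M[rr][c] = s / M[c][c];
          }
        }
        if (chol_ok) {
          for (int c = 0; c < f; ++c)
            for (int rr = 0; rr < f; ++rr)
              L[rr + c * BPP_MAXQ] = M[rr][c];
        }
      }

      if (!chol_ok) {
        // singular passive block: fall back to a pseudo-inverse solve
        uvec Fiv(f), Giv(gq);
        for (int i = 0; i < f; ++i) Fiv(i) = Fi[i];
        for (int i = 0; i < gq; ++i) Giv(i) = Gi[i];
        mat Aff = AtA.submat(Fiv, Fiv);
        mat Pi = pinv(Aff);
        for (int j = head[key]; j != -1; j = nxt[j]) {
          vec bf(f);
          for (int i = 0; i < f; ++i) bf(i) = b[Fi[i] + j * q];
          vec xf = Pi * bf;
          for (int i = 0; i < q; ++i) xy[i + j * q] = 0.0;
          for (int i = 0; i < f; ++i) xy[Fi[i] + j * q] = xf(i);
          for (int i = 0; i < gq; ++i) {
            double s = -b[Gi[i] + j * q];
            for (int k2 = 0; k2 < f; ++k2)
              s += a[Gi[i] + Fi[k2] * q] * xf(k2);
            xy[Gi[i] + j * q] = s;
          }
        }
        head[key] = -1;
        continue;
      }

      for (int j = head[key]; j != -1; j = nxt[j]) {
        double z[BPP_MAXQ];
        const double* bj = b + static_cast<size_t>(j) * q;
        // forward solve L z = b_F
        for (int i = 0; i < f; ++i) {
          double s = bj[Fi[i]];
          for (int k2 = 0; k2 < i; ++k2) s -= L[i + k2 * BPP_MAXQ] * z[k2];
          z[i] = s / L[i + i * BPP_MAXQ];
        }
        // back solve L' x = z
        for (int i = f - 1; i >= 0; --i) {
          double s = z[i];
          for (int k2 = i + 1; k2 < f; ++k2) s -= L[k2 + i * BPP_MAXQ] * z[k2];
          z[i] = s / L[i + i * BPP_MAXQ];
        }
        double* xyj = xy + static_cast<size_t>(j) * q;
        for (int i = 0; i < f; ++i) xyj[Fi[i]] = z[i];
        for (int i = 0; i < gq; ++i) {
          double s = -bj[Gi[i]];
          for (int k2 = 0; k2 < f; ++k2) s += a[Gi[i] + Fi[k2] * q] * z[k2];
          xyj[Gi[i]] = s;
        }
      }
      head[key] = -1;
    }

    // feasibility check and pivot-rule update of F
    for (int j = 0; j < r; ++j) {
      if (done[j]) continue;
      const double* xyj = xy + static_cast<size_t>(j) * q;
      int ninf = 0, last_bad = 0;
      for (int i = 0; i < q; ++i) {
        if (xyj[i] < -tol) { ++ninf; last_bad = i; }
      }
      if (ninf == 0) { done[j] = true; continue; }
      bool full_exchange;
      if (ninf < beta[j]) {
        beta[j] = ninf;
        alpha[j] = 3;
        full_exchange = true;
      } else if (alpha[j] > 0) {
        --alpha[j];
        full_exchange = true;
      } else {
        full_exchange = false;
      }
      if (full_exchange) {
        for (int i = 0; i < q; ++i)
          if (xyj[i] < -tol) F(i, j) = 1 - F(i, j);
      } else {
        F(last_bad, j) = 1 - F(last_bad, j);  // backup: largest index only
      }
    }
  }

  // assemble the primal solution: x on passive entries, 0 elsewhere
  for (int j = 0; j < r; ++j) {
    const double* xyj = xy + static_cast<size_t>(j) * q;
    for (int i = 0; i < q; ++i) {
      double v = F(i, j) ? xyj[i] : 0.0;
      X(i, j) = v < 0.0 ? 0.0 : v;
    }
  }
}

// [[Rcpp::export]]
arma::mat nnls_multi_cpp(const arma::mat& A, const arma::mat& B) {
  mat X;
  umat F(A.n_cols, B.n_cols, fill::ones);   // start from unconstrained
  nnls_bpp(A.t() * A, A.t() * B, X, F);
  return X;
}

// One ANLS run from a given non-negative initialisation of W.
// Stopping rules, checked each iteration:
//   * relative Frobenius residual ||V - WC|| / ||V|| < tol_res;
//   * residual progress: |rms_prev - rms| <= tol_res * max(1, rms_prev),
//     where rms is the per-element RMS residual (the classical
//     alternating-least-squares termination on the residual error);
//   * output variation: max relative change of the factor entries
//     between successive iterations < tol_change;
//   * max_iter reached.
// [[Rcpp::export]]
Rcpp::List anls_nmf_cpp(const arma::mat& V, arma::mat W, int max_iter,
                        double tol_res, double tol_change) {
  const double nV2 = accu(square(V));
  const double nV = std::sqrt(nV2);
  const double nm = static_cast<double>(V.n_rows) * V.n_cols;
  const uword k = W.n_cols;
  mat H(k, V.n_cols, fill::zeros);
  umat FH(k, V.n_cols, fill::ones);
  umat FW(k, V.n_rows, fill::ones);
  double rel = datum::inf;
  double rms_prev = datum::inf;
  int it = 0;
  bool converged = false;

  for (it = 1; it <= max_iter; ++it) {
    mat Wold = W;
    mat Hold = H;

    nnls_bpp(W.t() * W, W.t() * V, H, FH);
    mat HHt = H * H.t();
    mat HVt = H * V.t();
    mat Wt;
    nnls_bpp(HHt, HVt, Wt, FW);
    W = Wt.t();

    // ||V - WH||^2 from small byproducts of the W update
    double sse = nV2 - 2.0 * accu(W % HVt.t()) + accu((W * HHt) % W);
    sse = std::max(sse, 0.0);
    rel = std::sqrt(sse) / nV;
    double rms = std::sqrt(sse / nm);
    if (rel < tol_res) { converged = true; break; }
    if (it > 1) {
      if (std::abs(rms_prev - rms) <= tol_res * std::max(1.0, rms_prev)) {
        converged = true;
        break;
      }
      double sw = abs(Wold).max();
      double sh = abs(Hold).max();
      double dw = (sw > 0) ? abs(W - Wold).max() / sw : abs(W).max();
      double dh = (sh > 0) ? abs(H - Hold).max() / sh : abs(H).max();
      if (std::max(dw, dh) < tol_change) { converged = true; break; }
    }
    rms_prev = rms;
  }

  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("C") = H,
    Rcpp::Named("residual") = rel,
    Rcpp::Named("iterations") = std::min(it, max_iter),
    Rcpp::Named("converged") = converged);
}
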