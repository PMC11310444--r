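// Fast path for the EMU balance cascade: assembles and solves the per-size
// linear systems from precompiled index triplets. Mirrors the reference R
// implementation (solve_emu_system_r), which is kept for validation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec conv_open(const arma::vec& a, const arma::vec& b) {
  arma::vec out(a.n_elem + b.n_elem - 1, arma::fill::zeros);
  for (arma::uword i = 0; i < a.n_elem; ++i)
    for (arma::uword j = 0; j < b.n_elem; ++j) out[i + j] += a[i] * b[j];
  return out;
}

// [[Rcpp::export(name = ".emu_solve_cpp")]]
List emu_solve_cpp(List blocks, NumericVector uf, List mids, double ridge = 0.0) {
  List out(mids);
  for (int bi = 0; bi < blocks.size(); ++bi) {
    List blk = blocks[bi];
    int n = as<int>(blk["n"]);
    int k = as<int>(blk["size"]);
    List dg = blk["diag"];
    IntegerVector drow = dg["row"], duni = dg["uni"];
    NumericVector dw = dg["w"];
    arma::mat A(n, n, arma::fill::zeros);
    for (int i = 0; i < drow.size(); ++i)
      A(drow[i] - 1, drow[i] - 1) += dw[i] * uf[duni[i] - 1];
    for (int i = 0; i < n; ++i) {
      if (ridge > 0.0) {
        A(i, i) += ridge;
      } else if (A(i, i) <= 1e-12) {
        CharacterVector keys = blk["keys"];
        stop("singular EMU balance: zero consumption flux for pool of EMU %s",
             std::string(keys[i]));
      }
    }
    List am = blk["amat"];
    IntegerVector arow = am["row"], acol = am["col"], auni = am["uni"];
    NumericVector aw = am["w"];
    for (int i = 0; i < arow.size(); ++i)
      A(arow[i] - 1, acol[i] - 1) -= aw[i] * uf[auni[i] - 1];
    arma::mat RHS(n, k + 1, arma::fill::zeros);
    List rhs = blk["rhs"];
    for (int e = 0; e < rhs.size(); ++e) {
      List entry = rhs[e];
      double v = as<double>(entry["w"]) * uf[as<int>(entry["uni"]) - 1];
      if (v == 0.0) continue;
      IntegerVector src = entry["src"];
      arma::vec m = as<arma::vec>(out[src[0] - 1]);
      for (int s = 1; s < src.size(); ++s)
        m = conv_open(m, as<arma::vec>(out[src[s] - 1]));
      int row = as<int>(entry["row"]) - 1;
      for (int c = 0; c <= k; ++c) RHS(row, c) += v * m[c];
    }
    arma::mat X;
    bool ok = arma::solve(X, A, RHS, arma::solve_opts::no_approx);
    if (!ok) stop("singular EMU balance system at size %d (dead or unreachable pool)", k);
    IntegerVector ids = blk["ids"];
    for (int i = 0; i < n; ++i) {
      NumericVector xi(k + 1);
      for (int c = 0; c <= k; ++c) {
        double val = X(i, c);
        if (val < 0 && val > -1e-12) val = 0;
        xi[c] = val;
      }
      out[ids[i] - 1] = xi;
    }
  }
  return out;
}
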