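// Compiled fitting model: the EMU block structures, tracer inlet
// distributions and measurement layout are parsed once into a C++ object;
// each objective evaluation then only assembles and solves the per-size
// balance systems and returns the variance-weighted MID residuals.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct RhsEntry {
  int row;
  double w;
  int uni;
  std::vector<int> src;
};

struct Block {
  int n, k;
  std::vector<int> drow, duni;
  std::vector<double> dw;
  std::vector<int> arow, acol, auni;
  std::vector<double> aw;
  std::vector<RhsEntry> rhs;
  std::vector<int> ids;
};

struct FragPlan {
  bool mixed;
  int id, cyt, mito, mix;  // 0-based; mix indexes the mixing-fraction vector
};

struct TracerMeas {
  std::vector<arma::vec> inlets;  // by emu index; empty for unknowns
  std::vector<int> frag;          // 0-based fragment index per measurement
  std::vector<int> shift;         // 0-based mass shift per measurement
  arma::vec value, sd;
};

struct Model {
  std::vector<Block> blocks;
  int n_emus;
  std::vector<FragPlan> frags;
  std::vector<TracerMeas> tracers;
  double ridge;
};

arma::vec conv_open(const arma::vec& a, const arma::vec& b) {
  arma::vec out(a.n_elem + b.n_elem - 1, arma::fill::zeros);
  for (arma::uword i = 0; i < a.n_elem; ++i)
    for (arma::uword j = 0; j < b.n_elem; ++j) out[i + j] += a[i] * b[j];
  return out;
}

bool solve_blocks(const Model& m, const arma::vec& uf,
                  std::vector<arma::vec>& mids) {
  for (const Block& blk : m.blocks) {
    arma::mat A(blk.n, blk.n, arma::fill::zeros);
    for (size_t i = 0; i < blk.drow.size(); ++i)
      A(blk.drow[i], blk.drow[i]) += blk.dw[i] * uf[blk.duni[i]];
    for (int i = 0; i < blk.n; ++i) A(i, i) += m.ridge;
    for (size_t i = 0; i < blk.arow.size(); ++i)
      A(blk.arow[i], blk.acol[i]) -= blk.aw[i] * uf[blk.auni[i]];
    arma::mat RHS(blk.n, blk.k + 1, arma::fill::zeros);
    for (const RhsEntry& e : blk.rhs) {
      double v = e.w * uf[e.uni];
      if (v == 0.0) continue;
      arma::vec mid = mids[e.src[0]];
      for (size_t s = 1; s < e.src.size(); ++s)
        mid = conv_open(mid, mids[e.src[s]]);
      RHS.row(e.row) += (v * mid).t();
    }
    arma::mat X;
    if (!arma::solve(X, A, RHS, arma::solve_opts::no_approx)) return false;
    for (int i = 0; i < blk.n; ++i) {
      arma::vec xi = X.row(i).t();
      for (arma::uword c = 0; c < xi.n_elem; ++c)
        if (xi[c] < 0 && xi[c] > -1e-12) xi[c] = 0;
      mids[blk.ids[i]] = xi;
    }
  }
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".emu_fit_compile")]]
SEXP emu_fit_compile(List blocks, int n_emus, List frag_plan, List tracer_data,
                     double ridge) {
  Model* m = new Model();
  m->n_emus = n_emus;
  m->ridge = ridge;
  for (int bi = 0; bi < blocks.size(); ++bi) {
    List blk = blocks[bi];
    Block b;
    b.n = as<int>(blk["n"]);
    b.k = as<int>(blk["size"]);
    List dg = blk["diag"];
    IntegerVector drow = dg["row"], duni = dg["uni"];
    NumericVector dw = dg["w"];
    for (int i = 0; i < drow.size(); ++i) {
      b.drow.push_back(drow[i] - 1);
      b.duni.push_back(duni[i] - 1);
      b.dw.push_back(dw[i]);
    }
    List am = blk["amat"];
    IntegerVector arow = am["row"], acol = am["col"], auni = am["uni"];
    NumericVector aw = am["w"];
    for (int i = 0; i < arow.size(); ++i) {
      b.arow.push_back(arow[i] - 1);
      b.acol.push_back(acol[i] - 1);
      b.auni.push_back(auni[i] - 1);
      b.aw.push_back(aw[i]);
    }
    List rhs = blk["rhs"];
    for (int e = 0; e < rhs.size(); ++e) {
      List entry = rhs[e];
      RhsEntry re;
      re.row = as<int>(entry["row"]) - 1;
      re.w = as<double>(entry["w"]);
      re.uni = as<int>(entry["uni"]) - 1;
      IntegerVector src = entry["src"];
      for (int s = 0; s < src.size(); ++s) re.src.push_back(src[s] - 1);
      b.rhs.push_back(re);
    }
    IntegerVector ids = blk["ids"];
    for (int i = 0; i < ids.size(); ++i) b.ids.push_back(ids[i] - 1);
    m->blocks.push_back(b);
  }
  for (int fi = 0; fi < frag_plan.size(); ++fi) {
    List fp = frag_plan[fi];
    FragPlan f;
    f.mixed = as<bool>(fp["mixed"]);
    if (f.mixed) {
      f.cyt = as<int>(fp["cyt"]) - 1;
      f.mito = as<int>(fp["mito"]) - 1;
      f.mix = as<int>(fp["mix"]) - 1;
      f.id = -1;
    } else {
      f.id = as<int>(fp["id"]) - 1;
      f.cyt = f.mito = f.mix = -1;
    }
    m->frags.push_back(f);
  }
  for (int ti = 0; ti < tracer_data.size(); ++ti) {
    List td = tracer_data[ti];
    TracerMeas tm;
    List inl = td["inlets"];
    tm.inlets.resize(n_emus);
    for (int i = 0; i < inl.size(); ++i) {
      if (!Rf_isNull(inl[i])) tm.inlets[i] = as<arma::vec>(inl[i]);
    }
    IntegerVector frag = td["frag"], shift = td["shift"];
    for (int i = 0; i < frag.size(); ++i) {
      tm.frag.push_back(frag[i] - 1);
      tm.shift.push_back(shift[i] - 1);
    }
    tm.value = as<arma::vec>(td["value"]);
    tm.sd = as<arma::vec>(td["sd"]);
    m->tracers.push_back(tm);
  }
  XPtr<Model> ptr(m, true);
  return ptr;
}

// [[Rcpp::export(name = ".emu_fit_resid")]]
NumericVector emu_fit_resid(SEXP model_ptr, NumericVector uf_in,
                            NumericVector fmix) {
  XPtr<Model> m(model_ptr);
  arma::vec uf = as<arma::vec>(uf_in);
  int n_out = 0;
  for (const TracerMeas& tm : m->tracers) n_out += tm.value.n_elem;
  NumericVector out(n_out);
  int pos = 0;
  for (const TracerMeas& tm : m->tracers) {
    std::vector<arma::vec> mids = tm.inlets;
    bool ok = solve_blocks(*m, uf, mids);
    if (!ok) {
      for (arma::uword i = 0; i < tm.value.n_elem; ++i) out[pos++] = 1e4;
      continue;
    }
    std::vector<arma::vec> preds(m->frags.size());
    for (size_t fi = 0; fi < m->frags.size(); ++fi) {
      const FragPlan& f = m->frags[fi];
      if (f.mixed) {
        double w = fmix[f.mix];
        preds[fi] = w * mids[f.cyt] + (1 - w) * mids[f.mito];
      } else {
        preds[fi] = mids[f.id];
      }
    }
    for (arma::uword i = 0; i < tm.value.n_elem; ++i) {
      double pred = preds[tm.frag[i]][tm.shift[i]];
      out[pos++] = (pred - tm.value[i]) / tm.sd[i];
    }
  }
  return out;
}

// Forward-sensitivity residuals: returns the residual vector together with
// its exact Jacobian with respect to the unidirectional fluxes and the
// mixing fractions. Sensitivities solve the same per-size linear systems as
// the state (one factorization, many right-hand sides), so the Jacobian
// costs only a few state evaluations instead of one finite difference per
// parameter.
// [[Rcpp::export(name = ".emu_fit_jac")]]
List emu_fit_jac(SEXP model_ptr, NumericVector uf_in, NumericVector fmix) {
  XPtr<Model> m(model_ptr);
  arma::vec uf = as<arma::vec>(uf_in);
  const int nuf = uf.n_elem;
  const int nmix = fmix.size();
  int n_out = 0;
  for (const TracerMeas& tm : m->tracers) n_out += tm.value.n_elem;
  NumericVector res(n_out);
  arma::mat Juf(n_out, nuf, arma::fill::zeros);
  arma::mat Jf(n_out, nmix, arma::fill::zeros);
  int pos = 0;
  for (const TracerMeas& tm : m->tracers) {
    std::vector<arma::vec> mids = tm.inlets;
    std::vector<arma::mat> dmids(m->n_emus);  // (k+1) x nuf, zero for inlets
    for (int i = 0; i < m->n_emus; ++i) {
      if (mids[i].n_elem > 0) dmids[i].zeros(mids[i].n_elem, nuf);
    }
    bool ok = true;
    for (const Block& blk : m->blocks) {
      arma::mat A(blk.n, blk.n, arma::fill::zeros);
      for (size_t i = 0; i < blk.drow.size(); ++i)
        A(blk.drow[i], blk.drow[i]) += blk.dw[i] * uf[blk.duni[i]];
      for (int i = 0; i < blk.n; ++i) A(i, i) += m->ridge;
      for (size_t i = 0; i < blk.arow.size(); ++i)
        A(blk.arow[i], blk.acol[i]) -= blk.aw[i] * uf[blk.auni[i]];
      const int kk = blk.k + 1;
      arma::mat RHS(blk.n, kk, arma::fill::zeros);
      // big sensitivity RHS: column (j*kk + c)
      arma::mat DR(blk.n, kk * nuf, arma::fill::zeros);
      for (const RhsEntry& e : blk.rhs) {
        double v = e.w * uf[e.uni];
        // full convolution of the sources
        arma::vec full = mids[e.src[0]];
        for (size_t s = 1; s < e.src.size(); ++s)
          full = conv_open(full, mids[e.src[s]]);
        RHS.row(e.row) += (v * full).t();
        // d/duf_j of the flux factor
        for (int c = 0; c < kk; ++c)
          DR(e.row, e.uni * kk + c) += e.w * full[c];
        // d/duf of the source MIDs (product rule per source)
        for (size_t s = 0; s < e.src.size(); ++s) {
          if (v == 0.0) continue;
          const arma::mat& dm = dmids[e.src[s]];
          if (dm.n_elem == 0 || arma::accu(arma::abs(dm)) == 0) continue;
          if (e.src.size() == 1) {
            for (int j = 0; j < nuf; ++j)
              for (int c = 0; c < kk; ++c)
                DR(e.row, j * kk + c) += v * dm(c, j);
          } else {
            // convolution with the other sources as a linear (Toeplitz) map
            arma::vec other;
            bool first = true;
            for (size_t s2 = 0; s2 < e.src.size(); ++s2) {
              if (s2 == s) continue;
              other = first ? mids[e.src[s2]] : conv_open(other, mids[e.src[s2]]);
              first = false;
            }
            arma::mat contrib = v * arma::conv2(other, dm, "full");
            // conv2 of (len_o x 1) with (len_dm x nuf) gives (kk x nuf)
            for (int j = 0; j < nuf; ++j)
              for (int c = 0; c < kk; ++c)
                DR(e.row, j * kk + c) += contrib(c, j);
          }
        }
      }
      arma::mat X;
      if (!arma::solve(X, A, RHS, arma::solve_opts::no_approx)) { ok = false; break; }
      // dA X terms
      for (size_t i = 0; i < blk.drow.size(); ++i) {
        int r = blk.drow[i], j = blk.duni[i];
        for (int c = 0; c < kk; ++c) DR(r, j * kk + c) -= blk.dw[i] * X(r, c);
      }
      for (size_t i = 0; i < blk.arow.size(); ++i) {
        int r = blk.arow[i], j = blk.auni[i];
        for (int c = 0; c < kk; ++c) DR(r, j * kk + c) += blk.aw[i] * X(blk.acol[i], c);
      }
      arma::mat DX;
      if (!arma::solve(DX, A, DR, arma::solve_opts::no_approx)) { ok = false; break; }
      for (int i = 0; i < blk.n; ++i) {
        arma::vec xi = X.row(i).t();
        for (int c = 0; c < kk; ++c)
          if (xi[c] < 0 && xi[c] > -1e-12) xi[c] = 0;
        mids[blk.ids[i]] = xi;
        arma::mat dm(kk, nuf);
        for (int j = 0; j < nuf; ++j)
          for (int c = 0; c < kk; ++c) dm(c, j) = DX(i, j * kk + c);
        dmids[blk.ids[i]] = dm;
      }
    }
    if (!ok) {
      for (arma::uword i = 0; i < tm.value.n_elem; ++i) { res[pos] = 1e4; ++pos; }
      continue;
    }
    for (arma::uword i = 0; i < tm.value.n_elem; ++i) {
      const FragPlan& f = m->frags[tm.frag[i]];
      int sh = tm.shift[i];
      double pred, dpred_df = 0;
      arma::rowvec dpred;
      if (f.mixed) {
        double w = fmix[f.mix];
        pred = w * mids[f.cyt][sh] + (1 - w) * mids[f.mito][sh];
        dpred = w * dmids[f.cyt].row(sh) + (1 - w) * dmids[f.mito].row(sh);
        dpred_df = mids[f.cyt][sh] - mids[f.mito][sh];
      } else {
        pred = mids[f.id][sh];
        dpred = dmids[f.id].row(sh);
      }
      res[pos] = (pred - tm.value[i]) / tm.sd[i];
      Juf.row(pos) = dpred / tm.sd[i];
      if (f.mixed) Jf(pos, f.mix) = dpred_df / tm.sd[i];
      ++pos;
    }
  }
  return List::create(_["res"] = res, _["juf"] = Juf, _["jf"] = Jf);
}
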