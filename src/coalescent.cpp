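// Structured-coalescent simulator with piecewise-constant deme sizes,
// continuous migration and deme mergers, infinite-sites mutation.
// Time is measured in units of 2*N_ref generations (diffusion units);
// a deme of relative size nu coalesces pairs at rate 1/nu, a lineage in
// deme i migrates to deme j at rate M_ij = 2*N_ref*m_ij, and mutations
// fall on branches at rate theta/2 per unit length (theta = 4*N_ref*mu).
// Uses R's RNG so set.seed() in R governs reproducibility.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Lineage {
  int deme;
  double birth;
  std::vector<int> desc;       // descendant haploids per sampled population
  std::vector<uint64_t> bits;  // carrier mask over haploids (genotype mode)
};

struct Epoch {
  double duration;
  std::vector<double> nu;
  std::vector<std::vector<double>> mig;  // mig[i][j], i != j
  std::vector<int> map;                  // 0-based deme index in next epoch
};

}  // namespace

// [[Rcpp::export]]
List sim_coalescent_cpp(List epochs_r, IntegerVector sample_sizes,
                        int n_loci, double theta, bool return_genotypes) {
  const int n_pops = sample_sizes.size();
  int n_hap = 0;
  for (int p = 0; p < n_pops; ++p) n_hap += sample_sizes[p];
  const int n_words = (n_hap + 63) / 64;

  std::vector<Epoch> epochs;
  for (int e = 0; e < epochs_r.size(); ++e) {
    List el = epochs_r[e];
    Epoch ep;
    ep.duration = as<double>(el["duration"]);
    NumericVector nu = el["nu"];
    ep.nu.assign(nu.begin(), nu.end());
    NumericMatrix mg = el["mig"];
    int d = nu.size();
    ep.mig.assign(d, std::vector<double>(d, 0.0));
    for (int i = 0; i < d; ++i)
      for (int j = 0; j < d; ++j) ep.mig[i][j] = mg(i, j);
    if (el.containsElementNamed("map") && !Rf_isNull(el["map"])) {
      IntegerVector mp = el["map"];
      ep.map.assign(mp.begin(), mp.end());
      for (size_t k = 0; k < ep.map.size(); ++k) ep.map[k] -= 1;  // 1- to 0-based
    }
    epochs.push_back(ep);
  }

  // joint SFS accumulator, R column-major layout over dims (n_p + 1)
  std::vector<int> stride(n_pops);
  R_xlen_t n_cells = 1;
  for (int p = 0; p < n_pops; ++p) {
    stride[p] = (int)n_cells;
    n_cells *= (sample_sizes[p] + 1);
  }
  std::vector<double> sfs(n_cells, 0.0);

  // genotype-mode collectors
  std::vector<std::vector<uint64_t>> site_bits;
  std::vector<std::vector<int>> site_desc;

  RNGScope scope;

  for (int locus = 0; locus < n_loci; ++locus) {
    std::vector<Lineage> lin;
    lin.reserve(n_hap);
    int hap0 = 0;
    for (int p = 0; p < n_pops; ++p) {
      for (int h = 0; h < sample_sizes[p]; ++h) {
        Lineage L;
        L.deme = p;
        L.birth = 0.0;
        L.desc.assign(n_pops, 0);
        L.desc[p] = 1;
        if (return_genotypes) {
          L.bits.assign(n_words, 0ULL);
          int idx = hap0 + h;
          L.bits[idx / 64] |= (1ULL << (idx % 64));
        }
        lin.push_back(L);
      }
      hap0 += sample_sizes[p];
    }

    double t = 0.0;
    size_t ei = 0;
    double epoch_end = epochs[0].duration;  // absolute, since t starts at 0
    double epoch_start = 0.0;

    auto drop_mutations = [&](const Lineage &L, double t_top) {
      double len = t_top - L.birth;
      if (len <= 0.0 || theta <= 0.0) return;
      int nm = (int)R::rpois(0.5 * theta * len);
      if (nm == 0) return;
      R_xlen_t idx = 0;
      for (int p = 0; p < n_pops; ++p) idx += (R_xlen_t)L.desc[p] * stride[p];
      sfs[idx] += nm;
      if (return_genotypes) {
        for (int m = 0; m < nm; ++m) {
          site_bits.push_back(L.bits);
          site_desc.push_back(L.desc);
        }
      }
    };

    while (lin.size() > 1) {
      const Epoch &ep = epochs[ei];
      const int d = (int)ep.nu.size();
      std::vector<int> k(d, 0);
      for (size_t l = 0; l < lin.size(); ++l) k[lin[l].deme]++;

      double coal_tot = 0.0, mig_tot = 0.0;
      std::vector<double> coal_rate(d, 0.0), mig_rate(d, 0.0);
      for (int i = 0; i < d; ++i) {
        coal_rate[i] = 0.5 * k[i] * (k[i] - 1) / ep.nu[i];
        coal_tot += coal_rate[i];
        double mr = 0.0;
        for (int j = 0; j < d; ++j)
          if (j != i) mr += ep.mig[i][j];
        mig_rate[i] = k[i] * mr;
        mig_tot += mig_rate[i];
      }
      double total = coal_tot + mig_tot;
      if (total <= 0.0 && !R_FINITE(epoch_end))
        stop("no possible events remain: demography leaves lineages stranded");

      double wait = (total > 0.0) ? R::exp_rand() / total : R_PosInf;
      if (t + wait >= epoch_end) {
        // advance to boundary, remap demes
        t = epoch_end;
        for (size_t l = 0; l < lin.size(); ++l)
          lin[l].deme = ep.map[lin[l].deme];
        ++ei;
        epoch_start = epoch_end;
        epoch_end = R_FINITE(epochs[ei].duration)
                        ? epoch_start + epochs[ei].duration
                        : R_PosInf;
        continue;
      }
      t += wait;

      double u = unif_rand() * total;
      if (u < coal_tot) {
        int deme = 0;
        double acc = 0.0;
        for (; deme < d; ++deme) {
          acc += coal_rate[deme];
          if (u < acc) break;
        }
        // pick two distinct lineages in deme
        std::vector<int> idxs;
        for (size_t l = 0; l < lin.size(); ++l)
          if (lin[l].deme == deme) idxs.push_back((int)l);
        int a = (int)(unif_rand() * idxs.size());
        int b = (int)(unif_rand() * (idxs.size() - 1));
        if (b >= a) ++b;
        int la = idxs[a], lb = idxs[b];
        drop_mutations(lin[la], t);
        drop_mutations(lin[lb], t);
        Lineage merged;
        merged.deme = deme;
        merged.birth = t;
        merged.desc.assign(n_pops, 0);
        for (int p = 0; p < n_pops; ++p)
          merged.desc[p] = lin[la].desc[p] + lin[lb].desc[p];
        if (return_genotypes) {
          merged.bits.assign(n_words, 0ULL);
          for (int w = 0; w < n_words; ++w)
            merged.bits[w] = lin[la].bits[w] | lin[lb].bits[w];
        }
        int hi = std::max(la, lb), lo = std::min(la, lb);
        lin.erase(lin.begin() + hi);
        lin.erase(lin.begin() + lo);
        lin.push_back(merged);
      } else {
        u -= coal_tot;
        int deme = 0;
        double acc = 0.0;
        for (; deme < d; ++deme) {
          acc += mig_rate[deme];
          if (u < acc) break;
        }
        // pick a lineage in deme, then a destination
        std::vector<int> idxs;
        for (size_t l = 0; l < lin.size(); ++l)
          if (lin[l].deme == deme) idxs.push_back((int)l);
        int li = idxs[(int)(unif_rand() * idxs.size())];
        double mr = 0.0;
        for (int j = 0; j < d; ++j)
          if (j != deme) mr += ep.mig[deme][j];
        double v = unif_rand() * mr;
        int dest = -1;
        double acc2 = 0.0;
        for (int j = 0; j < d; ++j) {
          if (j == deme) continue;
          acc2 += ep.mig[deme][j];
          if (v < acc2) { dest = j; break; }
        }
        lin[li].deme = dest;
      }
    }
    if (locus % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  List out;
  IntegerVector dims(n_pops);
  for (int p = 0; p < n_pops; ++p) dims[p] = sample_sizes[p] + 1;
  NumericVector sfs_r(sfs.begin(), sfs.end());
  sfs_r.attr("dim") = dims;
  out["sfs"] = sfs_r;

  if (return_genotypes) {
    const R_xlen_t n_sites = (R_xlen_t)site_bits.size();
    IntegerMatrix hap(n_sites, n_hap);
    IntegerMatrix desc(n_sites, n_pops);
    for (R_xlen_t s = 0; s < n_sites; ++s) {
      for (int h = 0; h < n_hap; ++h)
        hap(s, h) = (site_bits[s][h / 64] >> (h % 64)) & 1ULL ? 1 : 0;
      for (int p = 0; p < n_pops; ++p) desc(s, p) = site_desc[s][p];
    }
    out["haplotypes"] = hap;
    out["site_counts"] = desc;
  }
  return out;
}
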