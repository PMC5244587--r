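#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Forward Wright-Fisher gamete formation.
//
// Haplotypes are columns of a raw (0/1) matrix whose rows are segregating
// sites. The first `n_sorted` rows hold the founder site registry, sorted by
// (chromosome block, position); rows n_sorted .. n_active-1 hold sites added
// by mutation in earlier generations, in arrival order (`extra_chrom`,
// `extra_pos`). Crossovers are Poisson per chromosome on the genetic map;
// chromosomes assort independently. New mutations arise per gamete at rate
// mu_site per site per generation, at uniform genomic positions, and occupy
// fresh rows up to the matrix's row capacity.
//
// Uses R's RNG throughout so results are reproducible under set.seed().

static int locate_block(const std::vector<double>& cum, double x) {
  // chromosome index for a global uniform draw over total length
  int n = (int)cum.size();
  for (int i = 0; i < n; ++i) if (x < cum[i]) return i;
  return n - 1;
}

// [[Rcpp::export(name = ".gametes_cpp")]]
List gametes_cpp(RawMatrix pop,
                 int n_sorted,
                 NumericVector pos_sorted,
                 IntegerVector block_start,     // length n_chrom + 1, 0-based row offsets
                 NumericVector chrom_len_bp,
                 NumericVector chrom_map_morgan,
                 IntegerVector extra_chrom,     // 0-based chromosome of mutation rows
                 NumericVector extra_pos,
                 IntegerVector parent_h1,       // 0-based haplotype column of each gamete's parent
                 IntegerVector parent_h2,
                 double mu_site) {
  const int cap = pop.nrow();
  const int n_gam = parent_h1.size();
  const int n_chrom = chrom_len_bp.size();
  int n_extra = extra_chrom.size();
  int n_active = n_sorted + n_extra;
  if (n_active > cap) stop("active sites exceed matrix capacity");

  double total_bp = 0.0;
  std::vector<double> cum_bp(n_chrom);
  for (int c = 0; c < n_chrom; ++c) { total_bp += chrom_len_bp[c]; cum_bp[c] = total_bp; }
  const double mu_gamete = mu_site * total_bp;

  RawMatrix out(cap, n_gam);  // zero-initialised
  std::vector<int> new_chrom;
  std::vector<double> new_pos;

  std::vector<std::vector<double>> bps(n_chrom);
  std::vector<int> start_hap(n_chrom);

  for (int g = 0; g < n_gam; ++g) {
    const Rbyte* h[2] = { &pop[(R_xlen_t)parent_h1[g] * cap],
                          &pop[(R_xlen_t)parent_h2[g] * cap] };
    Rbyte* dst = &out[(R_xlen_t)g * cap];

    for (int c = 0; c < n_chrom; ++c) {
      bps[c].clear();
      int cur = (unif_rand() < 0.5) ? 0 : 1;
      start_hap[c] = cur;
      int k = (int)R::rpois(chrom_map_morgan[c]);
      const int bs = block_start[c], be = block_start[c + 1];
      if (k == 0) {
        std::memcpy(dst + bs, h[cur] + bs, be - bs);
        continue;
      }
      for (int j = 0; j < k; ++j) bps[c].push_back(unif_rand() * chrom_len_bp[c]);
      std::sort(bps[c].begin(), bps[c].end());
      const double* p0 = &pos_sorted[0];
      int prev = bs;
      for (int j = 0; j < k; ++j) {
        int cut = (int)(std::lower_bound(p0 + bs, p0 + be, bps[c][j]) - p0);
        if (cut > prev) std::memcpy(dst + prev, h[cur] + prev, cut - prev);
        prev = cut;
        cur = 1 - cur;
      }
      if (be > prev) std::memcpy(dst + prev, h[cur] + prev, be - prev);
    }

    // mutation rows from previous generations: resolve source by breakpoint parity
    for (int e = 0; e < n_extra; ++e) {
      int c = extra_chrom[e];
      const std::vector<double>& b = bps[c];
      int n_before = (int)(std::upper_bound(b.begin(), b.end(), extra_pos[e]) - b.begin());
      int src = (start_hap[c] + n_before) % 2;
      dst[n_sorted + e] = h[src][n_sorted + e];
    }

    // new mutations on this gamete
    if (mu_gamete > 0) {
      int m = (int)R::rpois(mu_gamete);
      for (int j = 0; j < m; ++j) {
        int row = n_active + (int)new_chrom.size();
        if (row >= cap) stop("site capacity exhausted; increase capacity margin");
        double x = unif_rand() * total_bp;
        int c = locate_block(cum_bp, x);
        double offset = (c == 0) ? 0.0 : cum_bp[c - 1];
        new_chrom.push_back(c);
        new_pos.push_back(x - offset);
        out[(R_xlen_t)g * cap + row] = 1;
      }
    }
  }

  IntegerVector ec(n_extra + new_chrom.size());
  NumericVector ep(n_extra + new_pos.size());
  for (int e = 0; e < n_extra; ++e) { ec[e] = extra_chrom[e]; ep[e] = extra_pos[e]; }
  for (size_t j = 0; j < new_chrom.size(); ++j) {
    ec[n_extra + j] = new_chrom[j];
    ep[n_extra + j] = new_pos[j];
  }
  return List::create(_["geno"] = out, _["extra_chrom"] = ec, _["extra_pos"] = ep,
                      _["n_active"] = n_sorted + (int)ec.size());
}

// Allele counts (row sums over a set of haplotype columns), avoiding an R copy.
// [[Rcpp::export(name = ".hap_counts_cpp")]]
IntegerVector hap_counts_cpp(RawMatrix pop, IntegerVector cols, int n_rows) {
  IntegerVector out(n_rows);
  const int cap = pop.nrow();
  for (int j = 0; j < cols.size(); ++j) {
    const Rbyte* p = &pop[(R_xlen_t)cols[j] * cap];
    for (int i = 0; i < n_rows; ++i) out[i] += p[i];
  }
  return out;
}

// Multi-generation random-mating phase without mutation (used for the
// ancestral LD burn-in, where per-generation R-side allocation would
// dominate). n_males == 0 means monoecious random mating.
// [[Rcpp::export(name = ".wf_phase_cpp")]]
RawMatrix wf_phase_cpp(RawMatrix pop,
                       int n_sorted,
                       NumericVector pos_sorted,
                       IntegerVector block_start,
                       NumericVector chrom_len_bp,
                       NumericVector chrom_map_morgan,
                       int n_gens, int n_females, int n_males) {
  const int cap = pop.nrow();
  const int n_hap = pop.ncol();
  const int n_ind = n_hap / 2;
  const int n_chrom = chrom_len_bp.size();
  RawMatrix buf(cap, n_hap);
  RawMatrix cur = pop, nxt = buf;

  for (int gen = 0; gen < n_gens; ++gen) {
    for (int j = 0; j < n_ind; ++j) {
      for (int gidx = 0; gidx < 2; ++gidx) {
        int parent;
        if (n_males == 0) parent = (int)(unif_rand() * n_ind);
        else parent = (gidx == 0) ? (int)(unif_rand() * n_females)
                                  : n_females + (int)(unif_rand() * n_males);
        const Rbyte* h[2] = { &cur[(R_xlen_t)(2 * parent) * cap],
                              &cur[(R_xlen_t)(2 * parent + 1) * cap] };
        Rbyte* dst = &nxt[(R_xlen_t)(2 * j + gidx) * cap];
        for (int c = 0; c < n_chrom; ++c) {
          int curh = (unif_rand() < 0.5) ? 0 : 1;
          int k = (int)R::rpois(chrom_map_morgan[c]);
          const int bs = block_start[c], be = block_start[c + 1];
          if (k == 0) { std::memcpy(dst + bs, h[curh] + bs, be - bs); continue; }
          std::vector<double> bps(k);
          for (int x = 0; x < k; ++x) bps[x] = unif_rand() * chrom_len_bp[c];
          std::sort(bps.begin(), bps.end());
          const double* p0 = &pos_sorted[0];
          int prev = bs;
          for (int x = 0; x < k; ++x) {
            int cut = (int)(std::lower_bound(p0 + bs, p0 + be, bps[x]) - p0);
            if (cut > prev) std::memcpy(dst + prev, h[curh] + prev, cut - prev);
            prev = cut; curh = 1 - curh;
          }
          if (be > prev) std::memcpy(dst + prev, h[curh] + prev, be - prev);
        }
      }
    }
    std::swap(cur, nxt);
  }
  return cur;
}
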