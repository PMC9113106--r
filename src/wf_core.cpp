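#include <Rcpp.h>
#include <unordered_map>
#include <cstring>
using namespace Rcpp;

// Forward-in-time diploid Wright-Fisher core.
//
// Haplotypes are stored row-major per genomic element (independently
// assorting chromosome): hap[g][s] is the allele (0 ancestral / 1 derived)
// carried by haplotype g at the element's s-th segregating site. Individuals
// are ordered deme 0 first, then deme 1; individual i owns haplotype rows
// 2i and 2i+1. All randomness comes from R's RNG so that set.seed() on the
// R side makes runs bit-reproducible.

struct Elem {
  double len;                              // element length in bp
  std::vector<int> pos;                    // 1-based site positions
  std::vector<std::vector<uint8_t> > hap;  // n_hap rows x n_sites
  std::unordered_map<int, int> idx;        // position -> column
};

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static void reproduce(std::vector<Elem> &elems, int c0, int c1, int t0,
                      int t1, double m, double mu, double rec,
                      double total_len) {
  const int n_new = t0 + t1;
  const int n_gam = 2 * n_new;

  // Parent individual for every offspring gamete. A parent is drawn from
  // the offspring's own deme with probability 1 - m, from the other deme
  // with probability m; an empty deme redirects to the occupied one (this
  // is how a second deme is founded at a population split).
  std::vector<int> par(n_gam);
  for (int i = 0; i < n_new; ++i) {
    const int d = (i < t0) ? 0 : 1;
    for (int k = 0; k < 2; ++k) {
      int sd = d;
      if (m > 0.0 && unif_rand() < m) sd = 1 - sd;
      int avail = (sd == 0) ? c0 : c1;
      if (avail == 0) {
        sd = 1 - sd;
        avail = (sd == 0) ? c0 : c1;
      }
      const int p = runif_int(avail);
      par[2 * i + k] = (sd == 0) ? p : c0 + p;
    }
  }

  // Meiosis per element: free assortment between elements, Poisson
  // crossovers within an element at rate rec * length per gamete.
  for (size_t e = 0; e < elems.size(); ++e) {
    Elem &el = elems[e];
    const size_t S = el.pos.size();
    std::vector<uint8_t> base(n_gam);
    std::vector<std::vector<double> > cross(n_gam);
    const double xrate = rec * el.len;
    for (int g = 0; g < n_gam; ++g) {
      base[g] = (unif_rand() < 0.5) ? 1 : 0;
      if (rec > 0.0) {
        const int nc = (int)R::rpois(xrate);
        if (nc > 0) {
          cross[g].resize(nc);
          for (int j = 0; j < nc; ++j) cross[g][j] = unif_rand() * el.len;
        }
      }
    }
    std::vector<std::vector<uint8_t> > newhap(n_gam);
    for (int g = 0; g < n_gam; ++g) {
      newhap[g].reserve(S + 32);
      newhap[g].resize(S);
      const int p2 = 2 * par[g];
      if (cross[g].empty()) {
        if (S > 0)
          std::memcpy(newhap[g].data(), el.hap[p2 + base[g]].data(), S);
      } else {
        const std::vector<double> &cx = cross[g];
        for (size_t s = 0; s < S; ++s) {
          int k = 0;
          for (size_t j = 0; j < cx.size(); ++j)
            if (cx[j] < el.pos[s]) ++k;
          const uint8_t side = base[g] ^ (uint8_t)(k & 1);
          newhap[g][s] = el.hap[p2 + side][s];
        }
      }
    }
    el.hap.swap(newhap);
  }

  // Gamete mutations: finite-sites model, a hit on an already-segregating
  // position flips the allele (back mutation allowed).
  if (mu > 0.0) {
    const int nmut = (int)R::rpois(mu * total_len * n_gam);
    for (int j = 0; j < nmut; ++j) {
      double u = unif_rand() * total_len;
      size_t e = 0;
      while (e + 1 < elems.size() && u >= elems[e].len) {
        u -= elems[e].len;
        ++e;
      }
      Elem &el = elems[e];
      int p = (int)u + 1;
      if (p > (int)el.len) p = (int)el.len;
      const int g = runif_int(n_gam);
      std::unordered_map<int, int>::iterator it = el.idx.find(p);
      if (it != el.idx.end()) {
        el.hap[g][it->second] ^= 1;
      } else {
        const int col = (int)el.pos.size();
        for (int r = 0; r < n_gam; ++r)
          el.hap[r].push_back(r == g ? 1 : 0);
        el.pos.push_back(p);
        el.idx[p] = col;
      }
    }
  }
}

static void prune(std::vector<Elem> &elems, int n_gam) {
  for (size_t e = 0; e < elems.size(); ++e) {
    Elem &el = elems[e];
    const size_t S = el.pos.size();
    if (S == 0) continue;
    std::vector<int> sum(S, 0);
    for (int g = 0; g < n_gam; ++g) {
      const std::vector<uint8_t> &row = el.hap[g];
      for (size_t s = 0; s < S; ++s) sum[s] += row[s];
    }
    std::vector<int> keep;
    keep.reserve(S);
    for (size_t s = 0; s < S; ++s)
      if (sum[s] > 0 && sum[s] < n_gam) keep.push_back((int)s);
    if (keep.size() == S) continue;
    for (int g = 0; g < n_gam; ++g) {
      std::vector<uint8_t> &row = el.hap[g];
      for (size_t k = 0; k < keep.size(); ++k) row[k] = row[keep[k]];
      row.resize(keep.size());
    }
    std::vector<int> newpos(keep.size());
    el.idx.clear();
    for (size_t k = 0; k < keep.size(); ++k) {
      newpos[k] = el.pos[keep[k]];
      el.idx[newpos[k]] = (int)k;
    }
    el.pos.swap(newpos);
  }
}

// [[Rcpp::export]]
List wf_run_cpp(IntegerMatrix init_haps, IntegerMatrix init_sites,
                int n0_init, int n1_init, IntegerMatrix epochs,
                NumericVector epoch_m, double mu, double rec,
                NumericVector elem_len, bool prune_mono) {
  const int n_elem = elem_len.size();
  double total_len = 0.0;
  std::vector<Elem> elems(n_elem);
  for (int e = 0; e < n_elem; ++e) {
    elems[e].len = elem_len[e];
    total_len += elem_len[e];
  }

  int c0 = n0_init, c1 = n1_init;
  int n_gam = 2 * (c0 + c1);
  if (init_haps.nrow() != n_gam)
    stop("initial haplotype matrix must have 2 * (n0 + n1) rows");
  if (init_haps.ncol() != init_sites.nrow())
    stop("initial site table does not match haplotype matrix");

  for (int e = 0; e < n_elem; ++e)
    elems[e].hap.assign(n_gam, std::vector<uint8_t>());
  for (int s = 0; s < init_sites.nrow(); ++s) {
    const int e = init_sites(s, 0) - 1;
    if (e < 0 || e >= n_elem) stop("initial site element index out of range");
    Elem &el = elems[e];
    const int col = (int)el.pos.size();
    el.pos.push_back(init_sites(s, 1));
    el.idx[init_sites(s, 1)] = col;
    for (int g = 0; g < n_gam; ++g)
      el.hap[g].push_back((uint8_t)init_haps(g, s));
  }

  for (int ep = 0; ep < epochs.nrow(); ++ep) {
    const int n_gen = epochs(ep, 0);
    const int t0 = epochs(ep, 1);
    const int t1 = epochs(ep, 2);
    const double m = epoch_m[ep];
    if (n_gen < 1) stop("every epoch must span at least one generation");
    for (int g = 0; g < n_gen; ++g) {
      reproduce(elems, c0, c1, t0, t1, m, mu, rec, total_len);
      c0 = t0;
      c1 = t1;
      n_gam = 2 * (c0 + c1);
      if (prune_mono) prune(elems, n_gam);
    }
  }

  // Assemble output, columns ordered by (element, position).
  int S = 0;
  for (int e = 0; e < n_elem; ++e) S += (int)elems[e].pos.size();
  IntegerMatrix out_sites(S, 2);
  IntegerMatrix out_haps(n_gam, S);
  int col = 0;
  for (int e = 0; e < n_elem; ++e) {
    Elem &el = elems[e];
    std::vector<int> ord(el.pos.size());
    for (size_t s = 0; s < ord.size(); ++s) ord[s] = (int)s;
    std::sort(ord.begin(), ord.end(), [&el](int a, int b) {
      return el.pos[a] < el.pos[b];
    });
    for (size_t k = 0; k < ord.size(); ++k) {
      out_sites(col, 0) = e + 1;
      out_sites(col, 1) = el.pos[ord[k]];
      for (int g = 0; g < n_gam; ++g)
        out_haps(g, col) = el.hap[g][ord[k]];
      ++col;
    }
  }
  return List::create(_["sites"] = out_sites, _["haps"] = out_haps,
                      _["deme_sizes"] = IntegerVector::create(c0, c1));
}
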