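#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Barcode base equality: 'N' is a wildcard that matches nothing,
// including another 'N' (an unread base carries no evidence of identity).
static inline bool base_eq(char a, char b) {
  return a == b && a != 'N' && a != 'n';
}

// Banded Levenshtein distance, capped at k + 1 (early exit once the
// minimum of the current DP row exceeds k). DP buffers are reused across
// calls to avoid per-pair allocation.
static int bounded_lev(const char* a, int na, const char* b, int nb, int k) {
  if (na - nb > k || nb - na > k) return k + 1;
  // cheap prescreen for equal lengths: Levenshtein <= Hamming
  if (na == nb) {
    int h = 0;
    for (int i = 0; i < na && h <= k; ++i)
      if (!base_eq(a[i], b[i])) ++h;
    if (h <= k) return h;
  }
  static thread_local std::vector<int> prev, cur;
  prev.assign(nb + 1, 0);
  cur.assign(nb + 1, 0);
  for (int j = 0; j <= nb; ++j) prev[j] = j;
  for (int i = 1; i <= na; ++i) {
    cur[0] = i;
    int lo = i - k < 1 ? 1 : i - k;
    int hi = i + k > nb ? nb : i + k;
    int rowmin = cur[0];
    for (int j = 1; j <= nb; ++j) {
      if (j < lo || j > hi) { cur[j] = k + 1; continue; }
      int sub = prev[j - 1] + (base_eq(a[i - 1], b[j - 1]) ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      int v = sub < del ? sub : del;
      if (ins < v) v = ins;
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (rowmin > k) return k + 1;
    std::swap(prev, cur);
  }
  return prev[nb] > k ? k + 1 : prev[nb];
}

static int bounded_ham(const char* a, int na, const char* b, int nb, int k) {
  if (na != nb) return k + 1;
  int d = 0;
  for (int i = 0; i < na; ++i) {
    if (!base_eq(a[i], b[i])) {
      if (++d > k) return k + 1;
    }
  }
  return d;
}

// 2-bit packed representation of short ACGT-only barcodes (<= 16 nt)
// with per-base counts, enabling popcount Hamming and a character-count
// lower bound on the edit distance.
struct Packed {
  uint32_t bits;
  uint32_t cnt;
  bool valid;
};

static Packed pack_barcode(const char* s, int n) {
  Packed p = {0u, 0u, true};
  if (n < 1 || n > 16) { p.valid = false; return p; }
  int c[4] = {0, 0, 0, 0};
  for (int i = 0; i < n; ++i) {
    int v;
    switch (s[i]) {
      case 'A': v = 0; break;
      case 'C': v = 1; break;
      case 'G': v = 2; break;
      case 'T': v = 3; break;
      default: p.valid = false; return p;
    }
    p.bits |= ((uint32_t) v) << (2 * i);
    ++c[v];
  }
  p.cnt = (uint32_t) c[0] | ((uint32_t) c[1] << 8) |
          ((uint32_t) c[2] << 16) | ((uint32_t) c[3] << 24);
  return p;
}

static inline int packed_ham(uint32_t x, uint32_t y) {
  uint32_t v = x ^ y;
  v = (v | (v >> 1)) & 0x55555555u;
  return __builtin_popcount(v);
}

static inline int cnt_l1(uint32_t a, uint32_t b) {
  int s = 0;
  for (int k = 0; k < 4; ++k) {
    int da = (int) ((a >> (8 * k)) & 0xFFu);
    int db = (int) ((b >> (8 * k)) & 0xFFu);
    s += da > db ? da - db : db - da;
  }
  return s;
}

// Distance between barcodes i and j capped at k + 1, using the packed
// fast path when both are plain equal-length ACGT strings.
static int pair_dist(const char* a, int na, const Packed& pa,
                     const char* b, int nb, const Packed& pb,
                     int k, bool hamming) {
  if (pa.valid && pb.valid && na == nb) {
    int h = packed_ham(pa.bits, pb.bits);
    if (hamming || h <= k) return h > k ? k + 1 : h;
    // h > k: any cheaper alignment needs indels; each indel pair leaves
    // cnt_l1 <= 2 per unit of remaining budget
    int l1 = cnt_l1(pa.cnt, pb.cnt);
    if (l1 > 2 * k || (k == 2 && l1 > 2)) return k + 1;
    return bounded_lev(a, na, b, nb, k);
  }
  return hamming ? bounded_ham(a, na, b, nb, k)
                 : bounded_lev(a, na, b, nb, k);
}

struct UnionFind {
  std::vector<int> parent;
  UnionFind(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int x, int y) {
    int rx = find(x), ry = find(y);
    if (rx != ry) parent[rx < ry ? ry : rx] = rx < ry ? rx : ry;
  }
};

//' @title Barcode connected-component clustering (C++ kernel)
//' @description Links every pair of barcodes within \code{max_edit}
//'   (Levenshtein by default, Hamming optionally) and returns connected
//'   components, numbered by first appearance.
//' @param barcodes character vector of barcodes
//' @param max_edit maximum edit distance for a link
//' @param hamming use Hamming instead of Levenshtein distance
//' @return integer vector of 1-based component ids
//' @noRd
// [[Rcpp::export(name = ".umi_components_cpp")]]
IntegerVector umi_components_cpp(CharacterVector barcodes, int max_edit,
                                 bool hamming) {
  int n = barcodes.size();
  IntegerVector out(n);
  if (n == 0) return out;
  std::vector<const char*> s(n);
  std::vector<int> len(n);
  std::vector<Packed> pk(n);
  for (int i = 0; i < n; ++i) {
    s[i] = CHAR(STRING_ELT(barcodes, i));
    len[i] = (int) std::strlen(s[i]);
    pk[i] = pack_barcode(s[i], len[i]);
  }
  UnionFind uf(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (uf.find(i) == uf.find(j)) continue;
      int d = pair_dist(s[i], len[i], pk[i], s[j], len[j], pk[j],
                        max_edit, hamming);
      if (d <= max_edit) uf.unite(i, j);
    }
  }
  std::vector<int> relabel(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    if (relabel[r] == 0) relabel[r] = ++next;
    out[i] = relabel[r];
  }
  return out;
}

//' @title Position-aware barcode clustering (C++ kernel)
//' @description Links rows i, j iff |pos_i - pos_j| <= pos_tol AND the
//'   barcode edit distance is <= max_edit. `pos` must be sorted
//'   non-decreasingly. Returns connected components numbered by first
//'   appearance.
//' @noRd
// [[Rcpp::export(name = ".umi_components_pos_cpp")]]
IntegerVector umi_components_pos_cpp(CharacterVector barcodes,
                                     IntegerVector pos, int max_edit,
                                     int pos_tol, bool hamming) {
  int n = barcodes.size();
  if (pos.size() != n) stop("length mismatch");
  IntegerVector out(n);
  if (n == 0) return out;
  std::vector<const char*> s(n);
  std::vector<int> len(n);
  std::vector<Packed> pk(n);
  for (int i = 0; i < n; ++i) {
    s[i] = CHAR(STRING_ELT(barcodes, i));
    len[i] = (int) std::strlen(s[i]);
    pk[i] = pack_barcode(s[i], len[i]);
  }
  UnionFind uf(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n && pos[j] - pos[i] <= pos_tol; ++j) {
      if (uf.find(i) == uf.find(j)) continue;
      int d = pair_dist(s[i], len[i], pk[i], s[j], len[j], pk[j],
                        max_edit, hamming);
      if (d <= max_edit) uf.unite(i, j);
    }
  }
  std::vector<int> relabel(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    if (relabel[r] == 0) relabel[r] = ++next;
    out[i] = relabel[r];
  }
  return out;
}

//' @title Bounded pairwise barcode distance (C++ kernel)
//' @noRd
// [[Rcpp::export(name = ".umi_dist_cpp")]]
IntegerVector umi_dist_cpp(CharacterVector a, CharacterVector b, int cap,
                           bool hamming) {
  int n = a.size();
  if (b.size() != n) stop("length mismatch");
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* x = CHAR(STRING_ELT(a, i));
    const char* y = CHAR(STRING_ELT(b, i));
    int nx = (int) std::strlen(x), ny = (int) std::strlen(y);
    out[i] = hamming ? bounded_ham(x, nx, y, ny, cap)
                     : bounded_lev(x, nx, y, ny, cap);
  }
  return out;
}
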