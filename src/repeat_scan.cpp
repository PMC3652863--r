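// Exact maximal repeat scanner: seed (k-mer hash) and extend.
//
// Semantics shared with the package's documented definitions:
//  - direct:   s[p1..p1+l-1] == s[p2..p2+l-1], p1 < p2 (overlap allowed)
//  - inverted: s[p2..p2+l-1] == revcomp(s[p1..p1+l-1]), occurrences disjoint
//  - mirror:   s[p2..p2+l-1] == reverse(s[p1..p1+l-1]),  occurrences disjoint
// A hit is maximal when it cannot be extended on either side (for inverted /
// mirror, extension happens along the anti-diagonal p1 + p2 + l - 1 = const;
// a matched run that is symmetric about its centre is trimmed to the longest
// pair of disjoint occurrences, l = floor(run/2)).
// Only A/C/G/T positions can match; ambiguity codes never match anything.

#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <set>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T'; case 'T': return 'A';
    case 'G': return 'C'; case 'C': return 'G';
    default:  return 0;   // never matches
    }
}
static inline bool is_acgt(char c) {
    return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

struct Hit { int p1, p2, len; };

static bool hit_less(const Hit& a, const Hit& b) {
    if (a.len != b.len) return a.len > b.len;     // length desc
    if (a.p1 != b.p1) return a.p1 < b.p1;
    return a.p2 < b.p2;
}

// ---- direct repeats --------------------------------------------------------

static void scan_direct(const std::string& s, int k, std::vector<Hit>& hits) {
    const int n = (int) s.size();
    if (n < 2 * 1 || k > n) return;
    std::unordered_map<std::string, std::vector<int>> buckets;
    buckets.reserve(n * 2);
    for (int i = 0; i + k <= n; ++i) {
        bool ok = true;
        for (int j = i; j < i + k; ++j) if (!is_acgt(s[j])) { ok = false; break; }
        if (ok) buckets[s.substr(i, k)].push_back(i);
    }
    // diagonal -> intervals of occ1 starts already covered by a found hit
    std::map<int, std::vector<std::pair<int,int>>> seen;  // d -> (p1, len)
    std::set<std::pair<std::pair<int,int>, int>> uniq;
    for (auto& kv : buckets) {
        const std::vector<int>& pos = kv.second;
        for (size_t a = 0; a < pos.size(); ++a) {
            for (size_t b = a + 1; b < pos.size(); ++b) {
                int i = pos[a], j = pos[b];
                int d = j - i;
                bool covered = false;
                auto it = seen.find(d);
                if (it != seen.end()) {
                    for (auto& pr : it->second)
                        if (pr.first <= i && i + k <= pr.first + pr.second) {
                            covered = true; break;
                        }
                }
                if (covered) continue;
                int lo = i, hi = i + k - 1;   // occ1 run on diagonal d
                while (lo > 0 && lo + d > 0 && is_acgt(s[lo - 1]) &&
                       s[lo - 1] == s[lo - 1 + d]) --lo;
                while (hi + 1 < n && hi + 1 + d < n && is_acgt(s[hi + 1]) &&
                       s[hi + 1] == s[hi + 1 + d]) ++hi;
                int len = hi - lo + 1;
                seen[d].push_back(std::make_pair(lo, len));
                if (uniq.insert({{lo, lo + d}, len}).second)
                    hits.push_back({lo + 1, lo + d + 1, len});
            }
        }
    }
}

// ---- inverted / mirror repeats --------------------------------------------

// pred: does position q match position (c - q) on anti-diagonal c? (0-based)
static inline bool adiag_match(const std::string& s, int n, int c, int q,
                               bool complement) {
    int p = c - q;
    if (p < 0 || p >= n || q < 0 || q >= n) return false;
    if (!is_acgt(s[q]) || !is_acgt(s[p])) return false;
    return complement ? (s[q] == comp_base(s[p])) : (s[q] == s[p]);
}

static void scan_antidiag(const std::string& s, int k, bool complement,
                          std::vector<Hit>& hits) {
    const int n = (int) s.size();
    if (k > n) return;
    std::unordered_map<std::string, std::vector<int>> buckets;
    buckets.reserve(n * 2);
    for (int i = 0; i + k <= n; ++i) {
        bool ok = true;
        for (int j = i; j < i + k; ++j) if (!is_acgt(s[j])) { ok = false; break; }
        if (ok) buckets[s.substr(i, k)].push_back(i);
    }
    std::map<int, std::vector<std::pair<int,int>>> seen;  // c -> runs (x, y)
    std::set<std::pair<std::pair<int,int>, int>> uniq;
    for (auto& kv : buckets) {
        // partner k-mer whose occurrences pair with this one
        std::string partner(kv.first.rbegin(), kv.first.rend());
        if (complement)
            for (auto& ch : partner) ch = comp_base(ch);
        if (partner < kv.first) continue;        // enumerate each pair once
        auto pit = buckets.find(partner);
        if (pit == buckets.end()) continue;
        const std::vector<int>& P1 = kv.second;
        const std::vector<int>& P2 = pit->second;
        bool samebucket = (partner == kv.first);
        for (size_t a = 0; a < P1.size(); ++a) {
            size_t bstart = samebucket ? a : 0;   // i == j allowed (palindromes)
            for (size_t b = bstart; b < P2.size(); ++b) {
                int i = P1[a], j = P2[b];
                int c = i + j + k - 1;            // 0-based anti-diagonal
                int q0 = std::max(i, j);          // seed lies on run; use upper copy
                bool covered = false;
                auto it = seen.find(c);
                if (it != seen.end()) {
                    for (auto& pr : it->second)
                        if (pr.first <= q0 && q0 + k - 1 <= pr.second) {
                            covered = true; break;
                        }
                }
                if (covered) continue;
                // maximal matched run along anti-diagonal c containing q0
                int x = q0, y = q0 + k - 1;
                while (adiag_match(s, n, c, x - 1, complement)) --x;
                while (adiag_match(s, n, c, y + 1, complement)) ++y;
                seen[c].push_back(std::make_pair(x, y));
                int p1, p2, len;
                if (x == c - y) {                 // symmetric, centre-crossing run
                    int R = y - x + 1;
                    len = R / 2;
                    p1 = x;
                    p2 = y - len + 1;
                } else if (x + y > c) {           // run right of centre
                    p1 = c - y; p2 = x; len = y - x + 1;
                } else {                          // left of centre: mirror run
                    p1 = x; p2 = c - y; len = y - x + 1;
                }
                if (len < 1) continue;
                if (p1 + len - 1 >= p2) continue; // occurrences must be disjoint
                if (uniq.insert({{p1, p2}, len}).second)
                    hits.push_back({p1 + 1, p2 + 1, len});
            }
        }
    }
}

// [[Rcpp::export(name = ".scan_repeats_cpp")]]
DataFrame scan_repeats_cpp(std::string s, std::string kind, int min_len) {
    std::vector<Hit> hits;
    if (kind == "direct") scan_direct(s, min_len, hits);
    else if (kind == "inverted") scan_antidiag(s, min_len, true, hits);
    else if (kind == "mirror") scan_antidiag(s, min_len, false, hits);
    else stop("unknown repeat kind: %s", kind);
    // filter to min_len (trimmed symmetric runs can fall below it)
    std::vector<Hit> keep;
    for (auto& h : hits) if (h.len >= min_len) keep.push_back(h);
    std::sort(keep.begin(), keep.end(), hit_less);
    IntegerVector p1(keep.size()), p2(keep.size()), len(keep.size());
    for (size_t i = 0; i < keep.size(); ++i) {
        p1[i] = keep[i].p1; p2[i] = keep[i].p2; len[i] = keep[i].len;
    }
    return DataFrame::create(_["pos1"] = p1, _["pos2"] = p2,
                             _["length"] = len);
}
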