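#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Unit-cost global Levenshtein distance, single-row dynamic programme.
// Tags are short; the fixed stack buffer avoids per-call allocation.
#define LEV_STACK 128
static int lev(const char *a, int na, const char *b, int nb) {
    if (na == 0) return nb;
    if (nb == 0) return na;
    if (nb > LEV_STACK - 1 || na > LEV_STACK - 1) {
        // general path for long oligos
        std::vector<int> prev(nb + 1), cur(nb + 1);
        for (int j = 0; j <= nb; ++j) prev[j] = j;
        for (int i = 1; i <= na; ++i) {
            cur[0] = i;
            for (int j = 1; j <= nb; ++j) {
                int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
                cur[j] = std::min(sub, std::min(prev[j], cur[j - 1]) + 1);
            }
            std::swap(prev, cur);
        }
        return prev[nb];
    }
    int row[LEV_STACK];
    for (int j = 0; j <= nb; ++j) row[j] = j;
    for (int i = 1; i <= na; ++i) {
        int diag = row[0];
        row[0] = i;
        char ca = a[i - 1];
        for (int j = 1; j <= nb; ++j) {
            int sub = diag + (ca == b[j - 1] ? 0 : 1);
            diag = row[j];
            int v = std::min(sub, std::min(diag, row[j - 1]) + 1);
            row[j] = v;
        }
    }
    return row[nb];
}

// [[Rcpp::export(name = ".edit_dist_cpp")]]
IntegerVector edit_dist_cpp(CharacterVector a, CharacterVector b) {
    R_xlen_t n = a.size();
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const char *sa = CHAR(STRING_ELT(a, i));
        const char *sb = CHAR(STRING_ELT(b, i));
        out[i] = lev(sa, (int) strlen(sa), sb, (int) strlen(sb));
    }
    return out;
}

// [[Rcpp::export(name = ".hamming_dist_cpp")]]
IntegerVector hamming_dist_cpp(CharacterVector a, CharacterVector b) {
    R_xlen_t n = a.size();
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const char *sa = CHAR(STRING_ELT(a, i));
        const char *sb = CHAR(STRING_ELT(b, i));
        int na = (int) strlen(sa), nb = (int) strlen(sb);
        if (na != nb) stop("Hamming distance is undefined for unequal lengths");
        int d = 0;
        for (int j = 0; j < na; ++j) d += (sa[j] != sb[j]);
        out[i] = d;
    }
    return out;
}

// Full symmetric pairwise distance matrix over one pool of sequences.
// metric: 0 = edit, 1 = hamming.
// [[Rcpp::export(name = ".dist_matrix_cpp")]]
IntegerMatrix dist_matrix_cpp(CharacterVector x, int metric) {
    int n = (int) x.size();
    std::vector<std::string> s(n);
    for (int i = 0; i < n; ++i) s[i] = as<std::string>(x[i]);
    IntegerMatrix m(n, n);
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            int d;
            if (metric == 0) {
                d = lev(s[i].c_str(), (int) s[i].size(), s[j].c_str(), (int) s[j].size());
            } else {
                if (s[i].size() != s[j].size())
                    stop("Hamming distance is undefined for unequal lengths");
                d = 0;
                for (size_t k = 0; k < s[i].size(); ++k) d += (s[i][k] != s[j][k]);
            }
            m(i, j) = d;
            m(j, i) = d;
        }
    }
    return m;
}

// Per-key histogram of edit distances to every member of the pool
// (the summary vectors of the designer): row i, column d+1 holds the
// number of pool members at edit distance exactly d from keys[i].
// Keys are assumed to be a contiguous slice pool[first..first+nk-1]
// when symmetric = true (halves the work); otherwise arbitrary keys.
// [[Rcpp::export(name = ".count_by_distance_cpp")]]
IntegerMatrix count_by_distance_cpp(CharacterVector keys, CharacterVector pool,
                                    int max_d) {
    int nk = (int) keys.size(), np = (int) pool.size();
    std::vector<std::string> k(nk), p(np);
    for (int i = 0; i < nk; ++i) k[i] = as<std::string>(keys[i]);
    for (int i = 0; i < np; ++i) p[i] = as<std::string>(pool[i]);
    IntegerMatrix counts(nk, max_d + 1);
    for (int i = 0; i < nk; ++i) {
        for (int j = 0; j < np; ++j) {
            int d = lev(k[i].c_str(), (int) k[i].size(), p[j].c_str(), (int) p[j].size());
            if (d <= max_d) counts(i, d) += 1;
        }
        Rcpp::checkUserInterrupt();
    }
    return counts;
}

// Greedy lexicode construction around one key: scan the pool in its
// given order, drop candidates closer than min_d to the key, retain a
// candidate iff it is >= min_d from every previously retained one.
// Returns a logical keep-vector over the pool (the key itself, at
// distance zero, is never kept here and is prepended by the caller).
// [[Rcpp::export(name = ".greedy_build_cpp")]]
LogicalVector greedy_build_cpp(std::string key, CharacterVector pool, int min_d) {
    int np = (int) pool.size();
    std::vector<std::string> p(np);
    for (int i = 0; i < np; ++i) p[i] = as<std::string>(pool[i]);
    LogicalVector keep(np);
    std::vector<int> kept;
    kept.reserve(256);
    for (int i = 0; i < np; ++i) {
        int dk = lev(key.c_str(), (int) key.size(), p[i].c_str(), (int) p[i].size());
        if (dk < min_d) continue;
        bool ok = true;
        for (size_t j = 0; j < kept.size(); ++j) {
            int d = lev(p[kept[j]].c_str(), (int) p[kept[j]].size(),
                        p[i].c_str(), (int) p[i].size());
            if (d < min_d) { ok = false; break; }
        }
        if (ok) { keep[i] = true; kept.push_back(i); }
    }
    return keep;
}

// Edit distance from one query to every member of a pool.
// [[Rcpp::export(name = ".dist_to_pool_cpp")]]
IntegerVector dist_to_pool_cpp(std::string query, CharacterVector pool) {
    int np = (int) pool.size();
    IntegerVector out(np);
    for (int i = 0; i < np; ++i) {
        const char *sb = CHAR(STRING_ELT(pool, i));
        out[i] = lev(query.c_str(), (int) query.size(), sb, (int) strlen(sb));
    }
    return out;
}
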