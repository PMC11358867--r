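#include <Rcpp.h>
#include <algorithm>
#include <array>
using namespace Rcpp;

// Position order: 1 = alpha, 2-4 = arm 1 (beta, gamma, delta),
// 5-7 = arm 2, 8-10 = arm 3.  rho cycles the arms 1 -> 2 -> 3 and fixes
// alpha; sigma fixes alpha and arm 1 and swaps arms 2 and 3 site-wise.
// (0-based index arrays: new[p] = old[PERM[p]].)
static const std::array<int, 10> RHO   = {0, 7, 8, 9, 1, 2, 3, 4, 5, 6};
static const std::array<int, 10> SIGMA = {0, 1, 2, 3, 7, 8, 9, 4, 5, 6};

typedef std::array<int, 10> Bar;

static inline Bar permute(const Bar &b, const std::array<int, 10> &p) {
    Bar out;
    for (int i = 0; i < 10; ++i) out[i] = b[p[i]];
    return out;
}

// canonical form: the lexicographically greatest of the three arm rotations
// (pushes non-hydrogen digits towards arm 1).
static inline Bar canonical(const Bar &b) {
    Bar r1 = permute(b, RHO);
    Bar r2 = permute(r1, RHO);
    Bar best = b;
    if (r1 > best) best = r1;
    if (r2 > best) best = r2;
    return best;
}

static const char ALPHABET[] = "0123456789abcdefghijklmnopqrstuvwxyz";

// Scan every distinct permutation of a digit multiset (10 digits) and
// classify it under the C3 rotation group and the mirror reflection.
// Returns the counts needed by the isomer-counting oracle and, optionally,
// the canonical barcodes themselves.
// [[Rcpp::export(name = ".scan_barcodes")]]
List scan_barcodes(IntegerVector digits, bool collect = false) {
    if (digits.size() != 10)
        stop("a barcode digit multiset must have exactly 10 digits");
    Bar b;
    for (int i = 0; i < 10; ++i) {
        if (digits[i] < 0 || digits[i] > 35)
            stop("digit codes must lie in 0..35");
        b[i] = digits[i];
    }
    std::sort(b.begin(), b.end());

    double n_perm = 0;
    double n_canonical = 0, n_rho_invariant = 0, n_achiral = 0;
    std::vector<std::string> found;

    do {
        ++n_perm;
        Bar r1 = permute(b, RHO);
        if (b == r1) ++n_rho_invariant;
        Bar r2 = permute(r1, RHO);
        if (b >= r1 && b >= r2) {  // b is its own canonical form
            ++n_canonical;
            Bar m = canonical(permute(b, SIGMA));
            if (m == b) ++n_achiral;
            if (collect) {
                std::string s(10, '0');
                for (int i = 0; i < 10; ++i) s[i] = ALPHABET[b[i]];
                found.push_back(s);
            }
        }
    } while (std::next_permutation(b.begin(), b.end()));

    List out = List::create(
        _["n_permutations"]  = n_perm,
        _["n_canonical"]     = n_canonical,
        _["n_rho_invariant"] = n_rho_invariant,
        _["n_achiral"]       = n_achiral);
    if (collect) out["barcodes"] = wrap(found);
    return out;
}
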