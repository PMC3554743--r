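#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <stack>
using namespace Rcpp;

// Minimum-free-energy folding of a single RNA strand under a simplified
// nearest-neighbour model: stacking energies for adjacent canonical/wobble
// pairs, loop-size penalties for hairpin/bulge/internal loops (with
// logarithmic extrapolation beyond the tabulated sizes) and an affine
// multiloop term. Pseudoknot-free, O(n^3) interval DP with traceback.
//
// The R-level structure evaluator (structure_energy) implements the same
// decomposition independently; tests assert they agree.

static const int MAXLOOP = 30;   // max total unpaired bases in an interior loop
static const double INF = 1e9;

// base codes: A=0, C=1, G=2, U=3
// pair type indices: CG=0, GC=1, GU=2, UG=3, AU=4, UA=5, none=-1
static inline int pair_type(int a, int b) {
    if (a == 1 && b == 2) return 0;
    if (a == 2 && b == 1) return 1;
    if (a == 2 && b == 3) return 2;
    if (a == 3 && b == 2) return 3;
    if (a == 0 && b == 3) return 4;
    if (a == 3 && b == 0) return 5;
    return -1;
}

struct Params {
    double stack[6][6];
    std::vector<double> hairpin, bulge, internal_;
    double extrap, multi_offset, multi_branch, multi_unpaired;

    double loop_e(const std::vector<double>& tab, int L) const {
        int m = (int)tab.size();
        if (L <= 0) return INF;
        if (L <= m) return tab[L - 1];
        return tab[m - 1] + extrap * std::log((double)L / m);
    }
    double hairpin_e(int L) const { return loop_e(hairpin, L); }
    double bulge_e(int L) const { return loop_e(bulge, L); }
    double internal_e(int L) const { return loop_e(internal_, L); }
};

static Params read_params(List par) {
    Params p;
    NumericMatrix st = par["stack"];
    for (int i = 0; i < 6; ++i)
        for (int j = 0; j < 6; ++j) p.stack[i][j] = st(i, j);
    p.hairpin = as<std::vector<double> >(par["hairpin"]);
    p.bulge = as<std::vector<double> >(par["bulge"]);
    p.internal_ = as<std::vector<double> >(par["internal"]);
    p.extrap = as<double>(par["extrap"]);
    p.multi_offset = as<double>(par["multi_offset"]);
    p.multi_branch = as<double>(par["multi_branch"]);
    p.multi_unpaired = as<double>(par["multi_unpaired"]);
    return p;
}

// energy of the loop closed by (i,j) with single inner pair (k,l)
static inline double interior_e(const Params& p, const std::vector<int>& s,
                                int i, int j, int k, int l) {
    int l1 = k - i - 1, l2 = j - l - 1;
    if (l1 == 0 && l2 == 0)
        return p.stack[pair_type(s[i], s[j])][pair_type(s[k], s[l])];
    if (l1 == 0 || l2 == 0) return p.bulge_e(l1 + l2);
    return p.internal_e(l1 + l2);
}

// [[Rcpp::export]]
List fold_nn_cpp(IntegerVector seq, List par) {
    Params p = read_params(par);
    int n = seq.size();
    std::vector<int> s(seq.begin(), seq.end());
    if (n == 0)
        return List::create(_["structure"] = "", _["mfe"] = 0.0);

    std::vector<std::vector<double> > V(n, std::vector<double>(n, INF));
    std::vector<std::vector<double> > WM(n, std::vector<double>(n, INF));

    // WM spans must contain at least one branch; spans too short to hold
    // a pair stay at INF so "multiloops" cannot be branchless

    for (int d = 4; d < n; ++d) {           // j - i >= 4 (min hairpin loop 3)
        for (int i = 0; i + d < n; ++i) {
            int j = i + d;
            if (pair_type(s[i], s[j]) >= 0) {
                double best = p.hairpin_e(j - i - 1);
                // interior loops / stacks
                for (int k = i + 1; k <= i + 1 + MAXLOOP && k < j; ++k) {
                    int l2max = MAXLOOP - (k - i - 1);
                    for (int l = j - 1; l >= j - 1 - l2max && l > k; --l) {
                        if (l - k < 4) break;
                        if (V[k][l] >= INF / 2) continue;
                        double e = V[k][l] + interior_e(p, s, i, j, k, l);
                        if (e < best) best = e;
                    }
                }
                // multiloop closed by (i,j): >= 2 inner branches
                for (int k = i + 1; k < j - 1; ++k) {
                    if (WM[i + 1][k] >= INF / 2 || WM[k + 1][j - 1] >= INF / 2)
                        continue;
                    double e = WM[i + 1][k] + WM[k + 1][j - 1] +
                               p.multi_offset + p.multi_branch;
                    if (e < best) best = e;
                }
                V[i][j] = best;
            }
            // WM: >=1 branch inside a multiloop
            double wm = INF;
            if (i + 1 <= j && WM[i + 1][j] < INF / 2)
                wm = std::min(wm, WM[i + 1][j] + p.multi_unpaired);
            if (j - 1 >= i && WM[i][j - 1] < INF / 2)
                wm = std::min(wm, WM[i][j - 1] + p.multi_unpaired);
            if (V[i][j] < INF / 2)
                wm = std::min(wm, V[i][j] + p.multi_branch);
            for (int k = i; k < j; ++k) {
                if (WM[i][k] >= INF / 2 || WM[k + 1][j] >= INF / 2) continue;
                wm = std::min(wm, WM[i][k] + WM[k + 1][j]);
            }
            WM[i][j] = wm;
        }
    }
    // external: W[j] = mfe of prefix 0..j, unpaired bases free
    std::vector<double> W(n + 1, 0.0);
    std::vector<int> Wtb(n + 1, -1);        // -1: j unpaired; else i of pair (i,j)
    for (int j = 0; j < n; ++j) {
        double best = W[j];                 // base j+0.. unpaired (ties: fewer pairs)
        int tb = -1;
        for (int i = 0; i <= j - 4; ++i) {
            if (V[i][j] >= INF / 2) continue;
            double e = W[i] + V[i][j];
            if (e < best - 1e-12) { best = e; tb = i; }
        }
        W[j + 1] = best;
        Wtb[j + 1] = tb;
    }
    double mfe = W[n];

    // traceback
    std::vector<char> db(n, '.');
    std::stack<std::pair<std::pair<int, int>, int> > todo; // ((i,j), state) 0=V,1=WM
    {
        int j = n - 1;
        while (j >= 0) {
            int i = Wtb[j + 1];
            if (i < 0) { --j; continue; }
            todo.push(std::make_pair(std::make_pair(i, j), 0));
            j = i - 1;
        }
    }
    const double EPS = 1e-9;
    while (!todo.empty()) {
        int i = todo.top().first.first, j = todo.top().first.second;
        int state = todo.top().second;
        todo.pop();
        if (state == 0) {
            db[i] = '('; db[j] = ')';
            double v = V[i][j];
            if (std::fabs(v - p.hairpin_e(j - i - 1)) < EPS) continue;
            bool found = false;
            for (int k = i + 1; k <= i + 1 + MAXLOOP && k < j && !found; ++k) {
                int l2max = MAXLOOP - (k - i - 1);
                for (int l = j - 1; l >= j - 1 - l2max && l > k; --l) {
                    if (l - k < 4) break;
                    if (V[k][l] >= INF / 2) continue;
                    if (std::fabs(v - (V[k][l] + interior_e(p, s, i, j, k, l))) < EPS) {
                        todo.push(std::make_pair(std::make_pair(k, l), 0));
                        found = true; break;
                    }
                }
            }
            if (found) continue;
            for (int k = i + 1; k < j - 1 && !found; ++k) {
                if (WM[i + 1][k] >= INF / 2 || WM[k + 1][j - 1] >= INF / 2) continue;
                if (std::fabs(v - (WM[i + 1][k] + WM[k + 1][j - 1] +
                                   p.multi_offset + p.multi_branch)) < EPS) {
                    todo.push(std::make_pair(std::make_pair(i + 1, k), 1));
                    todo.push(std::make_pair(std::make_pair(k + 1, j - 1), 1));
                    found = true;
                }
            }
        } else {
            if (j < i) continue;
            double w = WM[i][j];
            if (j - i < 4) continue;        // all unpaired
            if (std::fabs(w - (WM[i + 1][j] + p.multi_unpaired)) < EPS) {
                todo.push(std::make_pair(std::make_pair(i + 1, j), 1));
                continue;
            }
            if (std::fabs(w - (WM[i][j - 1] + p.multi_unpaired)) < EPS) {
                todo.push(std::make_pair(std::make_pair(i, j - 1), 1));
                continue;
            }
            bool found = false;
            for (int k = i; k < j && !found; ++k) {
                if (WM[i][k] >= INF / 2 || WM[k + 1][j] >= INF / 2) continue;
                if (std::fabs(w - (WM[i][k] + WM[k + 1][j])) < EPS) {
                    todo.push(std::make_pair(std::make_pair(i, k), 1));
                    todo.push(std::make_pair(std::make_pair(k + 1, j), 1));
                    found = true;
                }
            }
            if (found) continue;
            if (V[i][j] < INF / 2 && std::fabs(w - (V[i][j] + p.multi_branch)) < EPS)
                todo.push(std::make_pair(std::make_pair(i, j), 0));
        }
    }
    return List::create(_["structure"] = std::string(db.begin(), db.end()),
                        _["mfe"] = mfe);
}
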