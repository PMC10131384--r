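// EHH / iHH / iHS / xpEHH engine.
//
// EHH at extent j is the probability that two random carrier haplotypes are
// identical over the interval between the core and j (the core column itself
// is excluded from the identity comparison, so EHH at the core is exactly 1
// for every allele class, including the pooled class used by xpEHH).
// Extension stops in each direction at the first site where EHH drops below
// the cutoff; integration (trapezoid against physical bp) only uses
// trapezoids whose both endpoints are at or above the cutoff.
//
// Partition refinement keeps only haplotypes in groups of size >= 2:
// singletons can never rejoin a group and contribute nothing to EHH, so
// dropping them makes the per-site cost shrink as the curve decays.
#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// reason codes shared with the R side
enum Reason { OK = 0, MONOMORPHIC = 1, EDGE = 2, GAP = 3, ZERO_AREA = 4 };

struct Arm {
  std::vector<int> idx;      // site indices (0-based), core first
  std::vector<double> ehh;   // EHH values, 1 at the core
  bool edge;                 // hit the chromosome edge with EHH >= cutoff
  bool gap;                  // inter-site gap > max_gap before cutoff reached
};

// one refinement step: split each group by the allele at site j, drop
// singletons, and return the sum of C(k,2) over surviving groups.
// active/grp are parallel vectors (haplotype row, its group id).
static double refine_step(const IntegerMatrix &H, int j,
                          std::vector<int> &active, std::vector<int> &grp,
                          int &ngrp, std::vector<int> &scratch) {
  const int n = (int)active.size();
  scratch.assign(2 * ngrp, -1);
  std::vector<int> cnt;
  int nnew = 0;
  for (int i = 0; i < n; ++i) {
    int key = 2 * grp[i] + (H(active[i], j) ? 1 : 0);
    if (scratch[key] < 0) {
      scratch[key] = nnew++;
      cnt.push_back(0);
    }
    grp[i] = scratch[key];
    ++cnt[grp[i]];
  }
  double s = 0;
  for (int c : cnt) s += 0.5 * (double)c * (c - 1);
  // compact away singleton groups
  int keep = 0;
  std::vector<int> remap(nnew, -1);
  int ng2 = 0;
  for (int i = 0; i < n; ++i) {
    if (cnt[grp[i]] >= 2) {
      if (remap[grp[i]] < 0) remap[grp[i]] = ng2++;
      active[keep] = active[i];
      grp[keep] = remap[grp[i]];
      ++keep;
    }
  }
  active.resize(keep);
  grp.resize(keep);
  ngrp = ng2 > 0 ? ng2 : 1;
  return s;
}

// partition refinement along one arm for one carrier set
static Arm walk_arm(const IntegerMatrix &H, const IntegerVector &pos,
                    const std::vector<int> &carriers, int core, int dir,
                    double cutoff, double max_gap) {
  Arm arm;
  arm.edge = false;
  arm.gap = false;
  const int n = (int)carriers.size();
  const int nsites = H.ncol();
  const double npairs = 0.5 * n * (n - 1);
  arm.idx.push_back(core);
  arm.ehh.push_back(1.0);
  std::vector<int> active = carriers;
  std::vector<int> grp(n, 0), scratch;
  int ngrp = 1;
  int prev = core;
  for (int j = core + dir; j >= 0 && j < nsites; j += dir) {
    if (max_gap > 0 && std::abs((double)pos[j] - (double)pos[prev]) > max_gap) {
      arm.gap = true;
      return arm;
    }
    double s = refine_step(H, j, active, grp, ngrp, scratch);
    double e = s / npairs;
    arm.idx.push_back(j);
    arm.ehh.push_back(e);
    if (e < cutoff) return arm; // first below-cutoff point recorded, then stop
    prev = j;
  }
  arm.edge = true; // ran off the chromosome with EHH still >= cutoff
  return arm;
}

// trapezoid integral of one arm; only both-endpoints-above-cutoff trapezoids
static double arm_area(const Arm &arm, const IntegerVector &pos, double cutoff) {
  double area = 0;
  for (size_t k = 0; k + 1 < arm.idx.size(); ++k) {
    double e0 = arm.ehh[k], e1 = arm.ehh[k + 1];
    if (e0 < cutoff || e1 < cutoff) break;
    area += 0.5 * (e0 + e1) *
            std::abs((double)pos[arm.idx[k + 1]] - (double)pos[arm.idx[k]]);
  }
  return area;
}

// [[Rcpp::export(name = ".ehh_curve_cpp")]]
List ehh_curve_cpp(IntegerMatrix H, IntegerVector pos, int core,
                   IntegerVector carriers, double cutoff, double max_gap) {
  std::vector<int> car(carriers.begin(), carriers.end());
  Arm left = walk_arm(H, pos, car, core, -1, cutoff, max_gap);
  Arm right = walk_arm(H, pos, car, core, +1, cutoff, max_gap);
  return List::create(
      _["left_idx"] = wrap(left.idx), _["left_ehh"] = wrap(left.ehh),
      _["left_edge"] = left.edge, _["left_gap"] = left.gap,
      _["right_idx"] = wrap(right.idx), _["right_ehh"] = wrap(right.ehh),
      _["right_edge"] = right.edge, _["right_gap"] = right.gap);
}

// unstandardized iHS = ln(iHH_ancestral / iHH_derived) per qualifying core
// [[Rcpp::export(name = ".ihs_scan_cpp")]]
List ihs_scan_cpp(IntegerMatrix H, IntegerVector pos, double cutoff,
                  double max_gap, int min_carriers) {
  const int nhap = H.nrow(), nsites = H.ncol();
  NumericVector score(nsites, NA_REAL);
  IntegerVector reason(nsites, 0);
  for (int core = 0; core < nsites; ++core) {
    std::vector<int> anc, der;
    for (int i = 0; i < nhap; ++i)
      (H(i, core) ? der : anc).push_back(i);
    if ((int)anc.size() < min_carriers || (int)der.size() < min_carriers) {
      reason[core] = MONOMORPHIC;
      continue;
    }
    double ihh[2];
    int code = OK;
    const std::vector<int> *cls[2] = { &anc, &der };
    for (int c = 0; c < 2 && code == OK; ++c) {
      Arm l = walk_arm(H, pos, *cls[c], core, -1, cutoff, max_gap);
      Arm r = walk_arm(H, pos, *cls[c], core, +1, cutoff, max_gap);
      if (l.gap || r.gap) { code = GAP; break; }
      if (l.edge || r.edge) { code = EDGE; break; }
      ihh[c] = arm_area(l, pos, cutoff) + arm_area(r, pos, cutoff);
    }
    if (code == OK && (ihh[0] <= 0 || ihh[1] <= 0)) code = ZERO_AREA;
    reason[core] = code;
    if (code == OK) score[core] = std::log(ihh[0] / ihh[1]);
  }
  return List::create(_["score"] = score, _["reason"] = reason);
}

// pooled-allele EHH walk for two populations jointly: the truncation extent
// comes from the combined-sample EHH; each population's own EHH is then
// integrated over that shared extent. Haplotypes 0..na-1 are population a.
// [[Rcpp::export(name = ".xpehh_scan_cpp")]]
List xpehh_scan_cpp(IntegerMatrix Ha, IntegerMatrix Hb, IntegerVector pos,
                    double cutoff, double max_gap) {
  const int na = Ha.nrow(), nb = Hb.nrow(), nsites = Ha.ncol();
  NumericVector score(nsites, NA_REAL);
  IntegerVector reason(nsites, 0);
  const double pa = 0.5 * na * (na - 1), pb = 0.5 * nb * (nb - 1);
  const int n = na + nb;
  const double pc = 0.5 * n * (n - 1);
  std::vector<int> active, grp, scratch, cnt_a, cnt_b;
  for (int core = 0; core < nsites; ++core) {
    double area_a[2] = { 0, 0 }, area_b[2] = { 0, 0 };
    int code = OK;
    for (int d = 0; d < 2 && code == OK; ++d) {
      int dir = d == 0 ? -1 : +1;
      active.resize(n);
      for (int i = 0; i < n; ++i) active[i] = i;
      grp.assign(n, 0);
      int ngrp = 1;
      double e_a = 1.0, e_b = 1.0;
      int prev = core;
      for (int j = core + dir;; j += dir) {
        if (j < 0 || j >= nsites) { code = EDGE; break; }
        if (max_gap > 0 &&
            std::abs((double)pos[j] - (double)pos[prev]) > max_gap) {
          code = GAP;
          break;
        }
        // refine combined partition; track per-population group counts
        const int m = (int)active.size();
        scratch.assign(2 * ngrp, -1);
        cnt_a.clear();
        cnt_b.clear();
        int nnew = 0;
        for (int i = 0; i < m; ++i) {
          int row = active[i];
          int allele = row < na ? (Ha(row, j) ? 1 : 0)
                                : (Hb(row - na, j) ? 1 : 0);
          int key = 2 * grp[i] + allele;
          if (scratch[key] < 0) {
            scratch[key] = nnew++;
            cnt_a.push_back(0);
            cnt_b.push_back(0);
          }
          grp[i] = scratch[key];
          if (row < na) ++cnt_a[grp[i]]; else ++cnt_b[grp[i]];
        }
        double sa = 0, sb = 0, sc = 0;
        for (int g = 0; g < nnew; ++g) {
          sa += 0.5 * (double)cnt_a[g] * (cnt_a[g] - 1);
          sb += 0.5 * (double)cnt_b[g] * (cnt_b[g] - 1);
          double t = cnt_a[g] + cnt_b[g];
          sc += 0.5 * t * (t - 1);
        }
        double new_comb = sc / pc;
        double new_a = pa > 0 ? sa / pa : 0;
        double new_b = pb > 0 ? sb / pb : 0;
        if (new_comb < cutoff) break; // extent ends; below-cutoff point unused
        double w = 0.5 * std::abs((double)pos[j] - (double)pos[prev]);
        area_a[d] += w * (e_a + new_a);
        area_b[d] += w * (e_b + new_b);
        e_a = new_a;
        e_b = new_b;
        prev = j;
        // drop combined singletons (they contribute to no further pair)
        int keep = 0;
        std::vector<int> remap(nnew, -1);
        int ng2 = 0;
        for (int i = 0; i < m; ++i) {
          int g = grp[i];
          if (cnt_a[g] + cnt_b[g] >= 2) {
            if (remap[g] < 0) remap[g] = ng2++;
            active[keep] = active[i];
            grp[keep] = remap[g];
            ++keep;
          }
        }
        active.resize(keep);
        grp.resize(keep);
        ngrp = ng2 > 0 ? ng2 : 1;
      }
    }
    if (code == OK) {
      double ia = area_a[0] + area_a[1], ib = area_b[0] + area_b[1];
      if (ia <= 0 || ib <= 0) code = ZERO_AREA;
      else score[core] = std::log(ia / ib);
    }
    reason[core] = code;
  }
  return List::create(_["score"] = score, _["reason"] = reason);
}
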