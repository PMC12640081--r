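// Core engines: structured-coalescent simulation on a species network
// (one introgression edge and/or migration bands), Jukes-Cantor pruning
// likelihood with partial-update caching, the MSC-I coalescent density of a
// gene tree with hybrid parent-choice indicators, and a Metropolis-within-
// Gibbs MCMC kernel for quartet-scale introgression models.
//
// Time is measured in expected substitutions/site throughout.  In a
// population of size theta the coalescent rate for k lineages is
// k(k-1)/theta; the backward per-lineage migration rate of a band with
// rate M (migrants/generation) into recipient Y is 4M/theta_Y.  All
// randomness goes through R's RNG so set.seed() controls everything.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double Inf = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Species network / population structure
// ---------------------------------------------------------------------------

struct Pop {
  double lo, hi;     // time interval (hi = Inf for root population)
  int parent;        // pop lineages enter at hi (-1 for root / hybrid-low)
  int theta_idx;     // which theta parameter applies
  int lo_param, hi_param; // which tau parameter the boundary derives from (-1: fixed)
};

struct Band {         // forward migration from -> to; backward jumps to->from
  int from_pop, to_pop;
  double rate_per_lineage; // 4M/theta_to
  double lo, hi;
};

struct Net {
  int nsp;                        // number of species-tree nodes
  std::vector<int> sp_parent;     // -1 for root
  std::vector<double> sp_age;     // 0 for extant species tips
  std::vector<double> theta;      // per node = branch above node (root: root pop)
  bool has_hybrid;
  int rec, donor;                 // species nodes whose branch carries the edge
  double tau_h, phi;
  std::vector<int> tau_param_of;  // sp node -> tau parameter index (-1 for tips)
  int tauh_param;                 // tau parameter index of tau_h (-1 if none)

  // raw band spec (species nodes); resolved to pops in build()
  struct RawBand { int from, to; double M, lo, hi; } ;
  std::vector<RawBand> raw_bands;

  std::vector<Pop> pops;
  std::vector<int> sp2pop;        // sp node -> pop at the node's own age
  int hy_pop, hy_main, hy_donor;  // hybrid-low pop, main continuation, donor pop
  std::vector<Band> bands;
  std::vector<double> btimes;     // sorted finite pop boundary times
  std::vector<std::vector<int> > bpops; // pops ending at each boundary time

  int pop_at(int spnode, double t) const {
    if (has_hybrid && spnode == rec)
      return (t < tau_h) ? hy_pop : hy_main;
    return sp2pop[spnode];
  }

  void build() {
    pops.clear(); sp2pop.assign(nsp, -1);
    hy_pop = hy_main = hy_donor = -1;
    for (int v = 0; v < nsp; v++) {
      double lo = sp_age[v];
      double hi = (sp_parent[v] < 0) ? Inf : sp_age[sp_parent[v]];
      int lo_par = tau_param_of[v];
      int hi_par = (sp_parent[v] < 0) ? -1 : tau_param_of[sp_parent[v]];
      if (has_hybrid && v == rec) {
        Pop plow  = {lo, tau_h, -1, v, lo_par, tauh_param};
        Pop phigh = {tau_h, hi, -1, v, tauh_param, hi_par};
        hy_pop = (int)pops.size(); pops.push_back(plow);
        hy_main = (int)pops.size(); pops.push_back(phigh);
        sp2pop[v] = hy_pop;
      } else {
        Pop p = {lo, hi, -1, v, lo_par, hi_par};
        sp2pop[v] = (int)pops.size(); pops.push_back(p);
      }
    }
    // parent links: lineages leaving pop of v at its hi enter the pop of
    // sp_parent[v] evaluated at that time
    for (int v = 0; v < nsp; v++) {
      int pr = sp_parent[v];
      int ptarget = (pr < 0) ? -1 : pop_at(pr, sp_age[pr]);
      if (has_hybrid && v == rec) {
        pops[hy_pop].parent = hy_main;   // main continuation (bit = 0)
        pops[hy_main].parent = ptarget;
      } else {
        pops[sp2pop[v]].parent = ptarget;
      }
    }
    if (has_hybrid) {
      hy_donor = pop_at(donor, tau_h);
      if (!(pops[hy_donor].lo < tau_h && tau_h < pops[hy_donor].hi))
        stop("introgression time lies outside the donor branch interval");
    }
    // migration bands resolved to pops
    bands.clear();
    for (size_t i = 0; i < raw_bands.size(); i++) {
      const RawBand& rb = raw_bands[i];
      int pf = sp2pop[rb.from], pt = sp2pop[rb.to];
      double lo = std::max(pops[pf].lo, pops[pt].lo);
      double hi = std::min(pops[pf].hi, pops[pt].hi);
      if (R_FINITE(rb.lo)) lo = std::max(lo, rb.lo);
      if (R_FINITE(rb.hi)) hi = std::min(hi, rb.hi);
      if (!(hi > lo)) stop("migration band has empty time window");
      if (!R_FINITE(hi)) stop("migration band window must be finite");
      Band b = {pf, pt, 4.0 * rb.M / theta[pops[pt].theta_idx], lo, hi};
      bands.push_back(b);
    }
    // boundary schedule
    btimes.clear(); bpops.clear();
    std::vector<std::pair<double,int> > ev;
    for (size_t p = 0; p < pops.size(); p++)
      if (R_FINITE(pops[p].hi)) ev.push_back(std::make_pair(pops[p].hi, (int)p));
    std::sort(ev.begin(), ev.end());
    for (size_t i = 0; i < ev.size(); i++) {
      if (btimes.empty() || ev[i].first > btimes.back()) {
        btimes.push_back(ev[i].first);
        bpops.push_back(std::vector<int>());
      }
      bpops.back().push_back(ev[i].second);
    }
  }
};

static Net net_from_list(List net_in) {
  Net net;
  net.sp_parent = as<std::vector<int> >(net_in["parent"]);
  net.sp_age    = as<std::vector<double> >(net_in["age"]);
  net.theta     = as<std::vector<double> >(net_in["theta"]);
  net.nsp = (int)net.sp_parent.size();
  net.has_hybrid = as<bool>(net_in["has_hybrid"]);
  net.rec = net.donor = -1; net.tau_h = 0.0; net.phi = 0.0;
  if (net.has_hybrid) {
    net.rec   = as<int>(net_in["recipient"]);
    net.donor = as<int>(net_in["donor"]);
    net.tau_h = as<double>(net_in["tau_h"]);
    net.phi   = as<double>(net_in["phi"]);
  }
  // tau parameter indexing: internal species nodes in index order, then tau_h
  net.tau_param_of.assign(net.nsp, -1);
  int k = 0;
  for (int v = 0; v < net.nsp; v++)
    if (net.sp_age[v] > 0.0) net.tau_param_of[v] = k++;
  net.tauh_param = net.has_hybrid ? k : -1;
  if (net_in.containsElementNamed("bands") && !Rf_isNull(net_in["bands"])) {
    NumericMatrix bm = net_in["bands"];
    for (int i = 0; i < bm.nrow(); i++) {
      Net::RawBand rb = {(int)bm(i,0), (int)bm(i,1), bm(i,2), bm(i,3), bm(i,4)};
      net.raw_bands.push_back(rb);
    }
  }
  net.build();
  return net;
}

// ---------------------------------------------------------------------------
// Gene-tree simulation (backward in time, competing exponentials per epoch)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_sim_gene_tree(List net_in, IntegerVector tip_sp) {
  Net net = net_from_list(net_in);
  int nt = tip_sp.size();
  if (nt < 1) stop("at least one sampled lineage required");
  int nn = 2 * nt - 1;
  std::vector<int> parent(nn, -1), bits(nn, 0), crossed(nn, 0);
  std::vector<double> age(nn, 0.0);
  std::vector<int> active, curpop(nn, -1);
  for (int i = 0; i < nt; i++) {
    int sp = tip_sp[i];
    if (sp < 0 || sp >= net.nsp) stop("tip species index out of range");
    curpop[i] = net.pop_at(sp, 0.0);
    active.push_back(i);
  }
  int next_node = nt;
  double t = 0.0;
  size_t bi = 0;
  std::vector<double> jump_time; std::vector<int> jump_node, jump_from, jump_to;
  int npop = (int)net.pops.size();
  std::vector<int> kpop(npop, 0);
  for (size_t i = 0; i < active.size(); i++) kpop[curpop[active[i]]]++;

  int guard = 0;
  while ((int)active.size() > 1 || bi < net.btimes.size()) {
    if (++guard > 100000000) stop("simulation failed to terminate");
    double tb = (bi < net.btimes.size()) ? net.btimes[bi] : Inf;
    // total rates in the current epoch
    double rc = 0.0;
    for (int p = 0; p < npop; p++)
      if (kpop[p] > 1) rc += kpop[p] * (kpop[p] - 1) / net.theta[net.pops[p].theta_idx];
    double rm = 0.0;
    for (size_t b = 0; b < net.bands.size(); b++)
      if (t >= net.bands[b].lo && t < net.bands[b].hi)
        rm += kpop[net.bands[b].to_pop] * net.bands[b].rate_per_lineage;
    double Rtot = rc + rm;
    double dt = (Rtot > 0) ? exp_rand() / Rtot : Inf;
    if (t + dt >= tb) {
      // process boundary: pops ending at tb
      t = tb;
      const std::vector<int>& ending = net.bpops[bi];
      for (size_t e = 0; e < ending.size(); e++) {
        int p = ending[e];
        for (size_t i = 0; i < active.size(); i++) {
          int ln = active[i];
          if (curpop[ln] != p) continue;
          int dest;
          if (net.has_hybrid && p == net.hy_pop) {
            int bit = (unif_rand() < net.phi) ? 1 : 0;
            bits[ln] = bit; crossed[ln] = 1;
            dest = bit ? net.hy_donor : net.hy_main;
          } else {
            dest = net.pops[p].parent;
          }
          kpop[p]--; kpop[dest]++; curpop[ln] = dest;
        }
      }
      bi++;
      continue;
    }
    t += dt;
    double u = unif_rand() * Rtot;
    if (u < rc) { // coalescence
      int p = -1;
      for (int q = 0; q < npop; q++) {
        if (kpop[q] > 1) {
          double r = kpop[q] * (kpop[q] - 1) / net.theta[net.pops[q].theta_idx];
          if (u < r) { p = q; break; }
          u -= r;
        }
      }
      if (p < 0) p = npop - 1;
      // pick an unordered pair uniformly in pop p
      std::vector<int> inp;
      for (size_t i = 0; i < active.size(); i++)
        if (curpop[active[i]] == p) inp.push_back(active[i]);
      int i1 = (int)(unif_rand() * inp.size());
      int i2 = (int)(unif_rand() * (inp.size() - 1));
      if (i2 >= i1) i2++;
      int c1 = inp[i1], c2 = inp[i2];
      int v = next_node++;
      parent[c1] = v; parent[c2] = v; age[v] = t; curpop[v] = p;
      active.erase(std::remove(active.begin(), active.end(), c1), active.end());
      active.erase(std::remove(active.begin(), active.end(), c2), active.end());
      active.push_back(v);
      kpop[p]--;
    } else { // migration jump (backward: recipient -> donor)
      u -= rc;
      int b = -1;
      for (size_t q = 0; q < net.bands.size(); q++) {
        if (t >= net.bands[q].lo && t < net.bands[q].hi) {
          double r = kpop[net.bands[q].to_pop] * net.bands[q].rate_per_lineage;
          if (u < r) { b = (int)q; break; }
          u -= r;
        }
      }
      if (b < 0) b = (int)net.bands.size() - 1;
      int pt = net.bands[b].to_pop, pf = net.bands[b].from_pop;
      std::vector<int> inp;
      for (size_t i = 0; i < active.size(); i++)
        if (curpop[active[i]] == pt) inp.push_back(active[i]);
      int ln = inp[(int)(unif_rand() * inp.size())];
      curpop[ln] = pf; kpop[pt]--; kpop[pf]++;
      jump_node.push_back(ln); jump_time.push_back(t);
      jump_from.push_back(pt); jump_to.push_back(pf);
    }
  }
  return List::create(
    _["parent"] = wrap(parent), _["age"] = wrap(age),
    _["bits"] = wrap(bits), _["crossed"] = wrap(crossed),
    _["n_jumps"] = (int)jump_node.size(),
    _["jump_node"] = wrap(jump_node), _["jump_time"] = wrap(jump_time),
    _["final_pop_theta_idx"] = (int)(active.empty() ? -1 :
        net.pops[curpop[active[0]]].theta_idx));
}

// Core of cpp_sim_gene_tree without the R conversion, for bulk Monte Carlo.
static void sim_core(const Net& net, const std::vector<int>& tip_pops,
                     std::vector<int>& parent, std::vector<double>& age,
                     int& n_jumps) {
  int nt = (int)tip_pops.size(), nn = 2*nt - 1;
  parent.assign(nn, -1); age.assign(nn, 0.0);
  n_jumps = 0;
  std::vector<int> active, curpop(nn, -1);
  int npop = (int)net.pops.size();
  std::vector<int> kpop(npop, 0);
  for (int i = 0; i < nt; i++) {
    curpop[i] = tip_pops[i]; active.push_back(i); kpop[tip_pops[i]]++;
  }
  int next_node = nt;
  double t = 0.0; size_t bi = 0;
  while ((int)active.size() > 1 || bi < net.btimes.size()) {
    double tb = (bi < net.btimes.size()) ? net.btimes[bi] : Inf;
    double rc = 0.0;
    for (int p = 0; p < npop; p++)
      if (kpop[p] > 1) rc += kpop[p]*(kpop[p]-1)/net.theta[net.pops[p].theta_idx];
    double rm = 0.0;
    for (size_t b = 0; b < net.bands.size(); b++)
      if (t >= net.bands[b].lo && t < net.bands[b].hi)
        rm += kpop[net.bands[b].to_pop] * net.bands[b].rate_per_lineage;
    double Rtot = rc + rm;
    double dt = (Rtot > 0) ? exp_rand() / Rtot : Inf;
    if (t + dt >= tb) {
      t = tb;
      const std::vector<int>& ending = net.bpops[bi];
      for (size_t e = 0; e < ending.size(); e++) {
        int p = ending[e];
        for (size_t i = 0; i < active.size(); i++) {
          int ln = active[i];
          if (curpop[ln] != p) continue;
          int dest;
          if (net.has_hybrid && p == net.hy_pop)
            dest = (unif_rand() < net.phi) ? net.hy_donor : net.hy_main;
          else dest = net.pops[p].parent;
          kpop[p]--; kpop[dest]++; curpop[ln] = dest;
        }
      }
      bi++; continue;
    }
    t += dt;
    double u = unif_rand() * Rtot;
    if (u < rc) {
      int p = npop - 1;
      for (int q = 0; q < npop; q++) {
        if (kpop[q] > 1) {
          double r = kpop[q]*(kpop[q]-1)/net.theta[net.pops[q].theta_idx];
          if (u < r) { p = q; break; }
          u -= r;
        }
      }
      std::vector<int> inp;
      for (size_t i = 0; i < active.size(); i++)
        if (curpop[active[i]] == p) inp.push_back(active[i]);
      int i1 = (int)(unif_rand() * inp.size());
      int i2 = (int)(unif_rand() * (inp.size() - 1));
      if (i2 >= i1) i2++;
      int c1 = inp[i1], c2 = inp[i2];
      int v = next_node++;
      parent[c1] = v; parent[c2] = v; age[v] = t; curpop[v] = p;
      active.erase(std::remove(active.begin(), active.end(), c1), active.end());
      active.erase(std::remove(active.begin(), active.end(), c2), active.end());
      active.push_back(v); kpop[p]--;
    } else {
      u -= rc;
      int b = (int)net.bands.size() - 1;
      for (size_t q = 0; q < net.bands.size(); q++) {
        if (t >= net.bands[q].lo && t < net.bands[q].hi) {
          double r = kpop[net.bands[q].to_pop] * net.bands[q].rate_per_lineage;
          if (u < r) { b = (int)q; break; }
          u -= r;
        }
      }
      int pt = net.bands[b].to_pop, pf = net.bands[b].from_pop;
      std::vector<int> inp;
      for (size_t i = 0; i < active.size(); i++)
        if (curpop[active[i]] == pt) inp.push_back(active[i]);
      int ln = inp[(int)(unif_rand() * inp.size())];
      curpop[ln] = pf; kpop[pt]--; kpop[pf]++; n_jumps++;
    }
  }
}

// Bulk Monte Carlo: simulate `reps` gene trees and summarise each by the
// rooted-triplet topology of the first three tips (1: tips 1,2 first;
// 2: tips 1,3; 3: tips 2,3; NA with < 3 tips), the root age, and the number
// of migration jumps.
// [[Rcpp::export]]
NumericMatrix cpp_sim_quartet_mc(List net_in, IntegerVector tip_sp, int reps) {
  Net net = net_from_list(net_in);
  int nt = tip_sp.size();
  std::vector<int> tip_pops(nt);
  for (int i = 0; i < nt; i++) tip_pops[i] = net.pop_at(tip_sp[i], 0.0);
  NumericMatrix out(reps, 4);
  std::vector<int> parent; std::vector<double> age;
  for (int r = 0; r < reps; r++) {
    int nj;
    sim_core(net, tip_pops, parent, age, nj);
    int nn = (int)parent.size();
    double top = NA_REAL, ilen = NA_REAL;
    if (nt >= 3) {
      double best = Inf, deepest = 0.0; int arg = 0;
      int pairs[3][2] = {{0,1},{0,2},{1,2}};
      for (int q = 0; q < 3; q++) {
        // MRCA age of the pair
        std::vector<char> on(nn, 0);
        int x = pairs[q][0];
        while (x >= 0) { on[x] = 1; x = parent[x]; }
        x = pairs[q][1];
        while (x >= 0 && !on[x]) x = parent[x];
        double a = (x >= 0) ? age[x] : Inf;
        if (a < best) { best = a; arg = q + 1; }
        if (a > deepest) deepest = a;
      }
      top = arg;
      ilen = deepest - best; // internal branch of the rooted triplet
    }
    out(r, 0) = top;
    out(r, 1) = age[nn - 1] > 0 ? *std::max_element(age.begin(), age.end()) : 0.0;
    out(r, 2) = nj;
    out(r, 3) = ilen;
  }
  colnames(out) = CharacterVector::create("topology", "root_age", "n_jumps",
                                          "internal_length");
  return out;
}

// Bulk ABBA/BABA site-pattern counting: simulate `reps` datasets of L loci
// (gene tree + JC sites) for one sequence from each of the ordered taxa
// (P1, P2, P3, O) and count, per locus, the number of ABBA
// (s1==s4, s2==s3, s1!=s2) and BABA (s2==s4, s1==s3, s1!=s2) sites.
// Rows are (rep, locus) in row-major order; columns (abba, baba).
// [[Rcpp::export]]
IntegerMatrix cpp_sim_dstat_mc(List net_in, IntegerVector tip_sp, int L,
                               int n_sites, int reps) {
  Net net = net_from_list(net_in);
  int nt = tip_sp.size();
  if (nt != 4) stop("four taxa required");
  std::vector<int> tip_pops(nt);
  for (int i = 0; i < nt; i++) tip_pops[i] = net.pop_at(tip_sp[i], 0.0);
  IntegerMatrix out(reps * L, 2);
  std::vector<int> parent; std::vector<double> age;
  int s[7];
  for (int r = 0; r < reps; r++) {
    for (int l = 0; l < L; l++) {
      int nj;
      sim_core(net, tip_pops, parent, age, nj);
      int nn = (int)parent.size();
      // preorder and per-branch change probabilities
      double pch[7];
      int ord[7], top = 0;
      {
        int stack[7], sp = 0, root = -1;
        int c1[7], c2[7];
        for (int i = 0; i < nn; i++) c1[i] = c2[i] = -1;
        for (int i = 0; i < nn; i++) {
          if (parent[i] < 0) { root = i; continue; }
          if (c1[parent[i]] < 0) c1[parent[i]] = i; else c2[parent[i]] = i;
          pch[i] = 0.75 * (1.0 - std::exp(-4.0 * (age[parent[i]] - age[i]) / 3.0));
        }
        stack[sp++] = root;
        while (sp > 0) {
          int v = stack[--sp];
          ord[top++] = v;
          if (c1[v] >= 0) stack[sp++] = c1[v];
          if (c2[v] >= 0) stack[sp++] = c2[v];
        }
      }
      int abba = 0, baba = 0;
      for (int site = 0; site < n_sites; site++) {
        for (int oi = 0; oi < nn; oi++) {
          int v = ord[oi];
          if (parent[v] < 0) { s[v] = (int)(unif_rand() * 4.0); continue; }
          int ps = s[parent[v]];
          if (unif_rand() < pch[v]) {
            int alt = (int)(unif_rand() * 3.0);
            s[v] = (alt >= ps) ? alt + 1 : alt;
          } else s[v] = ps;
        }
        if (s[0] != s[1]) {
          if (s[0] == s[3] && s[1] == s[2]) abba++;
          else if (s[1] == s[3] && s[0] == s[2]) baba++;
        }
      }
      out(r * L + l, 0) = abba;
      out(r * L + l, 1) = baba;
    }
  }
  colnames(out) = CharacterVector::create("abba", "baba");
  return out;
}

// ---------------------------------------------------------------------------
// JC sequence simulation along a gene tree
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_sim_jc(IntegerVector parent, NumericVector age, int n_sites) {
  int nn = parent.size(), nt = (nn + 1) / 2;
  if (n_sites < 0) stop("n_sites must be >= 0");
  // preorder (parents before children), robust to age ties
  std::vector<std::vector<int> > ch(nn);
  int root = -1;
  for (int i = 0; i < nn; i++) {
    if (parent[i] < 0) root = i; else ch[parent[i]].push_back(i);
  }
  std::vector<int> ord; ord.reserve(nn);
  std::vector<int> stack; stack.push_back(root);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    ord.push_back(v);
    for (size_t j = 0; j < ch[v].size(); j++) stack.push_back(ch[v][j]);
  }
  std::vector<int> state(nn);
  IntegerMatrix out(nt, n_sites);
  std::vector<double> pchange(nn, 0.0);
  for (int i = 0; i < nn; i++) {
    if (parent[i] >= 0) {
      double b = age[parent[i]] - age[i];
      if (b < 0) stop("negative branch length");
      pchange[i] = 0.75 * (1.0 - std::exp(-4.0 * b / 3.0));
    }
  }
  for (int s = 0; s < n_sites; s++) {
    for (int oi = 0; oi < nn; oi++) {
      int v = ord[oi];
      if (parent[v] < 0) { state[v] = (int)(unif_rand() * 4.0); continue; }
      int ps = state[parent[v]];
      if (unif_rand() < pchange[v]) {
        int alt = (int)(unif_rand() * 3.0);
        state[v] = (alt >= ps) ? alt + 1 : alt;
      } else state[v] = ps;
    }
    for (int i = 0; i < nt; i++) out(i, s) = state[i];
  }
  return out;
}

// ---------------------------------------------------------------------------
// JC pruning likelihood (standalone, for arbitrary rooted trees with ages)
// ---------------------------------------------------------------------------

// mask: ntips x npat, 4-bit codes (A=1,C=2,G=4,T=8, ambiguity = union, N/-=15)
static double jc_loglik_core(const std::vector<int>& mask,
                             const std::vector<double>& wt, int nt, int npat,
                             const std::vector<int>& parent,
                             const std::vector<double>& age) {
  int nn = (int)parent.size();
  std::vector<std::vector<int> > ch(nn);
  int root = -1;
  for (int i = 0; i < nn; i++) {
    if (parent[i] < 0) root = i; else ch[parent[i]].push_back(i);
  }
  // postorder (children before parents), robust to age ties
  std::vector<int> ord; ord.reserve(nn);
  {
    std::vector<int> stack; stack.push_back(root);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      ord.push_back(v);
      for (size_t j = 0; j < ch[v].size(); j++) stack.push_back(ch[v][j]);
    }
    std::reverse(ord.begin(), ord.end());
  }
  std::vector<double> clv((size_t)nn * npat * 4);
  for (int oi = 0; oi < nn; oi++) {
    int v = ord[oi];
    double* cv = &clv[(size_t)v * npat * 4];
    if (ch[v].empty()) {
      for (int s = 0; s < npat; s++) {
        int m = mask[(size_t)s * nt + v];
        for (int x = 0; x < 4; x++) cv[s*4+x] = (m >> x) & 1 ? 1.0 : 0.0;
      }
    } else {
      for (int s = 0; s < npat; s++)
        for (int x = 0; x < 4; x++) cv[s*4+x] = 1.0;
      for (size_t j = 0; j < ch[v].size(); j++) {
        int c = ch[v][j];
        double b = age[v] - age[c];
        if (b < 0) stop("negative branch length in gene tree");
        double e = std::exp(-4.0 * b / 3.0);
        const double* cc = &clv[(size_t)c * npat * 4];
        for (int s = 0; s < npat; s++) {
          double S = cc[s*4] + cc[s*4+1] + cc[s*4+2] + cc[s*4+3];
          for (int x = 0; x < 4; x++)
            cv[s*4+x] *= 0.25 * S + e * (cc[s*4+x] - 0.25 * S);
        }
      }
    }
  }
  double ll = 0.0;
  const double* rv = &clv[(size_t)root * npat * 4];
  for (int s = 0; s < npat; s++) {
    double site = 0.25 * (rv[s*4] + rv[s*4+1] + rv[s*4+2] + rv[s*4+3]);
    ll += wt[s] * std::log(site);
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_jc_loglik(IntegerMatrix mask, NumericVector wt,
                     IntegerVector parent, NumericVector age) {
  int nt = mask.nrow(), npat = mask.ncol();
  std::vector<int> m((size_t)nt * npat);
  for (int s = 0; s < npat; s++)
    for (int i = 0; i < nt; i++) m[(size_t)s * nt + i] = mask(i, s);
  return jc_loglik_core(m, as<std::vector<double> >(wt), nt, npat,
                        as<std::vector<int> >(parent),
                        as<std::vector<double> >(age));
}

// Unrooted quartet JC likelihood for topology topo (1: 12|34, 2: 13|24,
// 3: 14|23) with branch lengths b[0..3] terminal (taxa order) and b[4]
// internal.  Used by the exhaustive quartet ML search.
// [[Rcpp::export]]
double cpp_quartet_loglik(IntegerMatrix mask, NumericVector wt,
                          int topo, NumericVector b) {
  int npat = mask.ncol();
  int pair1[2], pair2[2];
  if (topo == 1)      { pair1[0]=0; pair1[1]=1; pair2[0]=2; pair2[1]=3; }
  else if (topo == 2) { pair1[0]=0; pair1[1]=2; pair2[0]=1; pair2[1]=3; }
  else if (topo == 3) { pair1[0]=0; pair1[1]=3; pair2[0]=1; pair2[1]=2; }
  else stop("topo must be 1, 2 or 3");
  double eb[5];
  for (int i = 0; i < 5; i++) eb[i] = std::exp(-4.0 * b[i] / 3.0);
  double ll = 0.0;
  for (int s = 0; s < npat; s++) {
    double tipv[4][4];
    for (int i = 0; i < 4; i++) {
      int m = mask(i, s);
      for (int x = 0; x < 4; x++) tipv[i][x] = (m >> x) & 1 ? 1.0 : 0.0;
    }
    double u[4], v[4];
    for (int x = 0; x < 4; x++) u[x] = v[x] = 1.0;
    for (int j = 0; j < 2; j++) {
      int t1 = pair1[j], t2 = pair2[j];
      double S1=0, S2=0;
      for (int x = 0; x < 4; x++) { S1 += tipv[t1][x]; S2 += tipv[t2][x]; }
      for (int x = 0; x < 4; x++) {
        u[x] *= 0.25*S1 + eb[t1]*(tipv[t1][x] - 0.25*S1);
        v[x] *= 0.25*S2 + eb[t2]*(tipv[t2][x] - 0.25*S2);
      }
    }
    // connect v across the internal branch into u, sum over root state at u
    double Sv = v[0]+v[1]+v[2]+v[3], site = 0.0;
    for (int x = 0; x < 4; x++)
      site += 0.25 * u[x] * (0.25*Sv + eb[4]*(v[x] - 0.25*Sv));
    ll += wt[s] * std::log(site);
  }
  return ll;
}

// ---------------------------------------------------------------------------
// ---------------------------------------------------------------------------
// MSC-I coalescent density of a gene tree
// ---------------------------------------------------------------------------
//
// The latent "parent choice" of each lineage that crosses the introgression
// time (donor path with probability phi, main path otherwise) couples with
// the gene tree through population compatibility.  coal_sweep() evaluates
// the density for one explicit assignment; coal_marginal() enumerates all
// 2^k assignments of the k crossing lineages and is what the MCMC kernel
// targets, so the sampler never has to move through the (heavily
// constrained) discrete choices one flip at a time.

struct SweepOut {
  bool ok;            // population-compatible
  double logw;        // coalescent core: excludes the phi factors
  std::vector<double> Sp; // per pop: sum k(k-1) dt
  std::vector<int> Cp;    // per pop: coalescence count
  int a_cnt, b_cnt;       // donor / main choices at the hybrid time
  std::vector<int> node_pop;
  std::vector<int> crossing;
  // persistent work buffers (avoid per-call allocation in the MCMC hot loop)
  std::vector<int> curpop, kpop, c1v, c2v, ord;
  std::vector<char> activef;

  // tree preparation (children + age-sorted internal nodes); shared across
  // the per-assignment sweeps of one marginalisation
  void prepare(const std::vector<int>& parent, const std::vector<double>& age) {
    int nn = (int)parent.size(), nt = (nn + 1) / 2;
    c1v.assign(nn, -1); c2v.assign(nn, -1);
    for (int i = 0; i < nn; i++) {
      int p = parent[i];
      if (p < 0) continue;
      if (c1v[p] < 0) c1v[p] = i; else c2v[p] = i;
    }
    ord.resize(nn - nt);
    for (int i = nt; i < nn; i++) ord[i - nt] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b){ return age[a] < age[b]; });
  }
};

// stop_after_hybrid: stop right after the introgression-time boundary has
// been processed (used to discover the crossing set; validity above the
// hybrid time is then not checked).  out.prepare() must have been called
// for the current (parent, age).
static bool coal_sweep(const Net& net, const std::vector<int>& parent,
                       const std::vector<double>& age,
                       const std::vector<int>& bits,
                       const std::vector<int>& tip_sp,
                       SweepOut& out, bool stop_after_hybrid = false) {
  int nn = (int)parent.size(), nt = (nn + 1) / 2;
  int npop = (int)net.pops.size();
  out.Sp.assign(npop, 0.0); out.Cp.assign(npop, 0);
  out.node_pop.assign(nn, -1); out.crossing.clear();
  out.a_cnt = out.b_cnt = 0; out.logw = 0.0; out.ok = true;
  out.curpop.assign(nn, -1);
  out.activef.assign(nn, 0);
  out.kpop.assign(npop, 0);
  for (int i = 0; i < nt; i++) {
    out.curpop[i] = net.pop_at(tip_sp[i], 0.0);
    out.node_pop[i] = out.curpop[i];
    out.activef[i] = 1; out.kpop[out.curpop[i]]++;
  }
  double t = 0.0, logd = 0.0;
  size_t bi = 0, ci = 0;
  const size_t nord = out.ord.size();
  while (bi < net.btimes.size() || ci < nord) {
    double tb = (bi < net.btimes.size()) ? net.btimes[bi] : Inf;
    double tc = (ci < nord) ? age[out.ord[ci]] : Inf;
    double tn = std::min(tb, tc);
    if (tn > t) {
      double dt = tn - t;
      for (int p = 0; p < npop; p++) {
        if (out.kpop[p] > 1) {
          double e = out.kpop[p] * (out.kpop[p] - 1) * dt;
          out.Sp[p] += e;
          logd -= e / net.theta[net.pops[p].theta_idx];
        }
      }
      t = tn;
    }
    if (tb <= tc) { // boundary first at ties
      bool was_hybrid = false;
      const std::vector<int>& ending = net.bpops[bi];
      for (size_t e = 0; e < ending.size(); e++) {
        int p = ending[e];
        if (net.has_hybrid && p == net.hy_pop) was_hybrid = true;
        if (out.kpop[p] == 0) continue;
        for (int i = 0; i < nn; i++) {
          if (!out.activef[i] || out.curpop[i] != p) continue;
          int dest;
          if (net.has_hybrid && p == net.hy_pop) {
            out.crossing.push_back(i);
            if (bits[i]) { out.a_cnt++; dest = net.hy_donor; }
            else         { out.b_cnt++; dest = net.hy_main; }
          } else dest = net.pops[p].parent;
          out.kpop[p]--; out.kpop[dest]++; out.curpop[i] = dest;
        }
      }
      bi++;
      if (stop_after_hybrid && was_hybrid) { out.logw = logd; return true; }
    } else { // coalescence
      int v = out.ord[ci++];
      int c1 = out.c1v[v], c2 = out.c2v[v];
      if (c1 < 0 || c2 < 0) return (out.ok = false);
      if (!out.activef[c1] || !out.activef[c2]) return (out.ok = false);
      int p = out.curpop[c1];
      if (p != out.curpop[c2]) return (out.ok = false);
      if (!(age[v] >= net.pops[p].lo && age[v] < net.pops[p].hi))
        return (out.ok = false);
      logd += std::log(2.0 / net.theta[net.pops[p].theta_idx]);
      out.Cp[p]++;
      out.activef[c1] = out.activef[c2] = 0; out.activef[v] = 1;
      out.curpop[v] = p; out.node_pop[v] = p;
      out.kpop[p]--;
    }
  }
  out.logw = logd;
  return true;
}

// [[Rcpp::export]]
List cpp_coal_logdensity(List net_in, IntegerVector parent, NumericVector age,
                         IntegerVector bits, IntegerVector tip_sp, double phi) {
  Net net = net_from_list(net_in);
  SweepOut out;
  std::vector<int> par = as<std::vector<int> >(parent);
  std::vector<double> ag = as<std::vector<double> >(age);
  out.prepare(par, ag);
  bool ok = coal_sweep(net, par, ag, as<std::vector<int> >(bits),
                       as<std::vector<int> >(tip_sp), out);
  if (!ok) stop("gene tree is incompatible with the species network");
  double logd = out.logw;
  if (net.has_hybrid) {
    if (out.a_cnt > 0) logd += (phi > 0) ? out.a_cnt * std::log(phi) : R_NegInf;
    if (out.b_cnt > 0) logd += (phi < 1) ? out.b_cnt * std::log1p(-phi) : R_NegInf;
  }
  return List::create(_["logdens"] = logd,
                      _["n_donor"] = out.a_cnt, _["n_main"] = out.b_cnt,
                      _["coal_counts"] = wrap(out.Cp),
                      _["exposure"] = wrap(out.Sp),
                      _["crossing"] = wrap(out.crossing));
}

// marginal over the 2^k parent-choice assignments
struct Marg {
  bool ok;
  int k, nass, nn, npop;
  std::vector<int> cross;    // crossing node ids (k)
  std::vector<char> valid;   // nass
  std::vector<double> logw;  // nass (theta-dependent coal core)
  std::vector<int> acnt;     // nass (# donor choices)
  std::vector<double> Sp;    // nass x npop
  std::vector<int> Cp;       // nass x npop
  std::vector<int> node_pop; // nass x nn
  std::vector<int> bits_scratch;
};

static bool coal_marginal(const Net& net, const std::vector<int>& parent,
                          const std::vector<double>& age,
                          const std::vector<int>& tip_sp, Marg& out,
                          SweepOut& scratch) {
  int nn = (int)parent.size();
  int npop = (int)net.pops.size();
  out.nn = nn; out.npop = npop;
  scratch.prepare(parent, age);
  out.bits_scratch.assign(nn, 0);
  std::vector<int>& bits = out.bits_scratch;
  if (!net.has_hybrid) {
    out.k = 0; out.nass = 1; out.cross.clear();
    bool ok = coal_sweep(net, parent, age, bits, tip_sp, scratch);
    out.valid.assign(1, ok && R_FINITE(scratch.logw));
    out.logw.assign(1, scratch.logw);
    out.acnt.assign(1, 0);
    out.Sp = scratch.Sp; out.Cp = scratch.Cp;
    out.node_pop = scratch.node_pop;
    out.ok = out.valid[0] != 0;
    return out.ok;
  }
  // discover the crossing set (determined by the tree below the hybrid time)
  if (!coal_sweep(net, parent, age, bits, tip_sp, scratch, true))
    return (out.ok = false);
  out.cross = scratch.crossing;
  out.k = (int)out.cross.size();
  if (out.k > 16) stop("too many lineages at the introgression time (k > 16)");
  out.nass = 1 << out.k;
  out.valid.assign(out.nass, 0);
  out.logw.assign(out.nass, R_NegInf);
  out.acnt.assign(out.nass, 0);
  out.Sp.assign((size_t)out.nass * npop, 0.0);
  out.Cp.assign((size_t)out.nass * npop, 0);
  out.node_pop.assign((size_t)out.nass * nn, -1);
  out.ok = false;
  for (int b = 0; b < out.nass; b++) {
    for (int j = 0; j < out.k; j++)
      bits[out.cross[j]] = (b >> j) & 1;
    bool ok = coal_sweep(net, parent, age, bits, tip_sp, scratch);
    if (!ok || !R_FINITE(scratch.logw)) continue;
    out.valid[b] = 1; out.ok = true;
    out.logw[b] = scratch.logw;
    out.acnt[b] = scratch.a_cnt;
    std::copy(scratch.Sp.begin(), scratch.Sp.end(),
              out.Sp.begin() + (size_t)b * npop);
    std::copy(scratch.Cp.begin(), scratch.Cp.end(),
              out.Cp.begin() + (size_t)b * npop);
    std::copy(scratch.node_pop.begin(), scratch.node_pop.end(),
              out.node_pop.begin() + (size_t)b * nn);
  }
  return out.ok;
}

// log sum_b valid w_b phi^a_b (1-phi)^(k-a_b)
static double marg_logdens(const Marg& m, double phi) {
  double lphi = (phi > 0) ? std::log(phi) : R_NegInf;
  double l1m  = (phi < 1) ? std::log1p(-phi) : R_NegInf;
  double mx = R_NegInf;
  for (int b = 0; b < m.nass; b++) {
    if (!m.valid[b]) continue;
    double v = m.logw[b];
    if (m.acnt[b] > 0) v += m.acnt[b] * lphi;
    if (m.k - m.acnt[b] > 0) v += (m.k - m.acnt[b]) * l1m;
    if (v > mx) mx = v;
  }
  if (!R_FINITE(mx)) return R_NegInf;
  double s = 0.0;
  for (int b = 0; b < m.nass; b++) {
    if (!m.valid[b]) continue;
    double v = m.logw[b];
    if (m.acnt[b] > 0) v += m.acnt[b] * lphi;
    if (m.k - m.acnt[b] > 0) v += (m.k - m.acnt[b]) * l1m;
    s += std::exp(v - mx);
  }
  return mx + std::log(s);
}

// draw one assignment from its conditional given the tree and phi
static int marg_draw(const Marg& m, double phi) {
  double lphi = (phi > 0) ? std::log(phi) : R_NegInf;
  double l1m  = (phi < 1) ? std::log1p(-phi) : R_NegInf;
  std::vector<double> w(m.nass, 0.0);
  double mx = R_NegInf;
  for (int b = 0; b < m.nass; b++) {
    if (!m.valid[b]) { w[b] = R_NegInf; continue; }
    w[b] = m.logw[b] + m.acnt[b] * ((m.acnt[b] > 0) ? lphi : 0.0)
         + (m.k - m.acnt[b]) * ((m.k - m.acnt[b] > 0) ? l1m : 0.0);
    if (w[b] > mx) mx = w[b];
  }
  double tot = 0.0;
  for (int b = 0; b < m.nass; b++)
    if (R_FINITE(w[b])) { w[b] = std::exp(w[b] - mx); tot += w[b]; }
    else w[b] = 0.0;
  double u = unif_rand() * tot;
  for (int b = 0; b < m.nass; b++) {
    if (u < w[b]) return b;
    u -= w[b];
  }
  for (int b = m.nass - 1; b >= 0; b--) if (m.valid[b]) return b;
  return 0;
}

// [[Rcpp::export]]
List cpp_coal_marginal(List net_in, IntegerVector parent, NumericVector age,
                       IntegerVector tip_sp, double phi) {
  Net net = net_from_list(net_in);
  Marg m; SweepOut sc;
  bool ok = coal_marginal(net, as<std::vector<int> >(parent),
                          as<std::vector<double> >(age),
                          as<std::vector<int> >(tip_sp), m, sc);
  if (!ok) stop("gene tree is incompatible with the species network");
  return List::create(_["logdens"] = marg_logdens(m, phi),
                      _["k"] = m.k, _["crossing"] = wrap(m.cross),
                      _["logw"] = wrap(m.logw), _["acnt"] = wrap(m.acnt),
                      _["valid"] = wrap(m.valid));
}

// ---------------------------------------------------------------------------
// MCMC kernel (Metropolis-within-Gibbs) for the MSC-I quartet model
// ---------------------------------------------------------------------------

struct Locus {
  int nt, nn, npat;
  std::vector<int> mask;      // npat * nt (pattern-major)
  std::vector<double> wt;
  std::vector<int> tip_sp;
  std::vector<int> parent;
  std::vector<double> age;
  std::vector<std::vector<int> > ch;
  std::vector<double> clv, clvp;  // nn*npat*4
  double loglik;
  Marg mg;        // marginal coalescent cache
  double logdens; // marg_logdens(mg, phi)
  // scratch
  Marg mgp;
  SweepOut sc;
  std::vector<double> agep;
  std::vector<int> dirty;
  std::vector<int> parentp;   // resimulation proposal scratch
  std::vector<double> agep2;
  std::vector<int> tip_pops;

  int root() const {
    for (int i = 0; i < nn; i++) if (parent[i] < 0) return i;
    return -1;
  }
  void rebuild_children() {
    ch.assign(nn, std::vector<int>());
    for (int i = 0; i < nn; i++) if (parent[i] >= 0) ch[parent[i]].push_back(i);
  }
  // recompute clvs for nodes in `dirty` (children-before-parents order)
  // into clvp, reading clean children from clv; returns new log-likelihood
  double recompute_dirty(const std::vector<double>& ages) {
    std::vector<char> isd(nn, 0);
    for (size_t i = 0; i < dirty.size(); i++) isd[dirty[i]] = 1;
    for (size_t di = 0; di < dirty.size(); di++) {
      int v = dirty[di];
      double* cv = &clvp[(size_t)v * npat * 4];
      if (ch[v].empty()) {
        for (int s = 0; s < npat; s++) {
          int m = mask[(size_t)s * nt + v];
          for (int x = 0; x < 4; x++) cv[s*4+x] = (m >> x) & 1 ? 1.0 : 0.0;
        }
        continue;
      }
      for (int s = 0; s < npat * 4; s++) cv[s] = 1.0;
      for (size_t j = 0; j < ch[v].size(); j++) {
        int c = ch[v][j];
        const double* cc = isd[c] ? &clvp[(size_t)c * npat * 4]
                                  : &clv[(size_t)c * npat * 4];
        double b = ages[v] - ages[c];
        if (b < 0) return R_NegInf;
        double e = std::exp(-4.0 * b / 3.0);
        for (int s = 0; s < npat; s++) {
          double S = cc[s*4] + cc[s*4+1] + cc[s*4+2] + cc[s*4+3];
          for (int x = 0; x < 4; x++)
            cv[s*4+x] *= 0.25*S + e * (cc[s*4+x] - 0.25*S);
        }
      }
    }
    int r = root();
    const double* rv = isd[r] ? &clvp[(size_t)r * npat * 4]
                              : &clv[(size_t)r * npat * 4];
    double ll = 0.0;
    for (int s = 0; s < npat; s++) {
      double site = 0.25 * (rv[s*4] + rv[s*4+1] + rv[s*4+2] + rv[s*4+3]);
      ll += wt[s] * std::log(site);
    }
    return ll;
  }
  void commit_dirty() {
    for (size_t i = 0; i < dirty.size(); i++) {
      int v = dirty[i];
      std::copy(clvp.begin() + (size_t)v*npat*4,
                clvp.begin() + (size_t)(v+1)*npat*4,
                clv.begin() + (size_t)v*npat*4);
    }
  }
  void path_dirty(int v) {
    dirty.clear();
    while (v >= 0) { dirty.push_back(v); v = parent[v]; }
  }
};

static double reflect(double x, double lo, double hi) {
  if (!R_FINITE(hi)) {
    if (x < lo) x = 2*lo - x;
    if (x < lo) x = lo;
    return x;
  }
  double w = hi - lo;
  if (w <= 0) return lo;
  double y = x - lo, period = 2*w;
  y -= std::floor(y / period) * period;
  return lo + (y <= w ? y : period - y);
}

struct Tuner {
  double step; long acc, tot, acc_all, tot_all;
  Tuner(double s): step(s), acc(0), tot(0), acc_all(0), tot_all(0) {}
  void hit(bool a) { tot++; tot_all++; if (a) { acc++; acc_all++; } }
  void adapt() {
    if (tot < 20) return;
    double r = (double)acc / tot;
    step *= (r > 0.3) ? 1.15 : 0.87;
    acc = tot = 0;
  }
  double rate() const { return tot_all ? (double)acc_all / tot_all : NA_REAL; }
};

// [[Rcpp::export]]
List cpp_mcmc_msci(List net_in, List loci_in, List init_in, List prior_in,
                   List set_in) {
  Net net = net_from_list(net_in);
  int nloci = loci_in.size();
  if ((int)LENGTH(init_in) != nloci) stop("init length mismatch");

  double a_th = as<double>(prior_in["theta_shape"]);
  double b_th = as<double>(prior_in["theta_rate"]);
  double a_ta = as<double>(prior_in["tau_shape"]);
  double b_ta = as<double>(prior_in["tau_rate"]);
  double a_ph = as<double>(prior_in["phi_a"]);
  double b_ph = as<double>(prior_in["phi_b"]);

  int burnin  = as<int>(set_in["burnin"]);
  int nsamp   = as<int>(set_in["nsamples"]);
  int thin    = as<int>(set_in["thin"]);
  int tau_every = as<int>(set_in["tau_every"]);
  int age_moves = as<int>(set_in["age_moves"]);
  int mix_every = set_in.containsElementNamed("mix_every")
    ? as<int>(set_in["mix_every"]) : 1;
  int resim_every = set_in.containsElementNamed("resim_every")
    ? as<int>(set_in["resim_every"]) : 1;

  std::vector<int> tau_nodes;
  for (int v = 0; v < net.nsp; v++)
    if (net.tau_param_of[v] >= 0) tau_nodes.push_back(v);
  int ntau = (int)tau_nodes.size();
  int ntaup = ntau + (net.has_hybrid ? 1 : 0);
  int root_sp = -1;
  for (int v = 0; v < net.nsp; v++) if (net.sp_parent[v] < 0) root_sp = v;
  int k_free = ntaup - 1; // non-root taus flat given root => prior ~ tauR^{-k}

  std::vector<Locus> loci(nloci);
  double phi = net.phi;
  for (int l = 0; l < nloci; l++) {
    List li = loci_in[l], ii = init_in[l];
    Locus& L = loci[l];
    IntegerMatrix mk = li["mask"];
    L.nt = mk.nrow(); L.npat = mk.ncol(); L.nn = 2*L.nt - 1;
    L.mask.resize((size_t)L.nt * L.npat);
    for (int s = 0; s < L.npat; s++)
      for (int i = 0; i < L.nt; i++) L.mask[(size_t)s*L.nt + i] = mk(i, s);
    L.wt = as<std::vector<double> >(li["wt"]);
    L.tip_sp = as<std::vector<int> >(li["tip_sp"]);
    L.parent = as<std::vector<int> >(ii["parent"]);
    L.age    = as<std::vector<double> >(ii["age"]);
    L.rebuild_children();
    L.clv.assign((size_t)L.nn * L.npat * 4, 0.0);
    L.clvp = L.clv;
    std::vector<int> all(L.nn);
    for (int i = 0; i < L.nn; i++) all[i] = i;
    std::sort(all.begin(), all.end(),
              [&](int a, int b){ return L.age[a] < L.age[b]; });
    L.dirty = all;
    L.loglik = L.recompute_dirty(L.age);
    L.commit_dirty();
    if (!R_FINITE(L.loglik)) stop("non-finite initial likelihood at a locus");
    if (!coal_marginal(net, L.parent, L.age, L.tip_sp, L.mg, L.sc))
      stop("initial gene tree incompatible with the species network");
    L.logdens = marg_logdens(L.mg, phi);
    if (!R_FINITE(L.logdens))
      stop("non-finite initial coalescent density at a locus");
    L.agep = L.age;
  }

  double base_tau = net.sp_age[root_sp] > 0 ? net.sp_age[root_sp]
                                            : 2.0 * a_th / b_th;
  Tuner t_age(0.5 * base_tau);
  Tuner t_th(0.5);
  std::vector<Tuner> t_tau(ntaup + (net.has_hybrid ? 3 : 0),
                           Tuner(0.2 * base_tau));
  Tuner t_nni(0), t_resim(0), t_mix(0.3);

  int niter = burnin + nsamp * thin;
  int npop = (int)net.pops.size();
  NumericMatrix trace(nsamp, ntaup + net.nsp + (net.has_hybrid ? 1 : 0) + 1);
  int srow = 0;

  for (int iter = 0; iter < niter; iter++) {
    if (iter % 256 == 0) Rcpp::checkUserInterrupt();
    bool adapt = iter < burnin;

    // ----- per-locus gene-tree moves -----
    for (int l = 0; l < nloci; l++) {
      Locus& L = loci[l];

      for (int rep = 0; rep < age_moves; rep++) {
        int v = L.nt + (int)(unif_rand() * (L.nn - L.nt));
        double lo = std::max(L.age[L.ch[v][0]], L.age[L.ch[v][1]]);
        double hi = (L.parent[v] >= 0) ? L.age[L.parent[v]] : Inf;
        if (hi - lo <= 0) continue;
        double prop = reflect(L.age[v] + (unif_rand()*2 - 1) * t_age.step, lo, hi);
        double old = L.age[v];
        L.agep = L.age; L.agep[v] = prop;
        bool accept = false;
        if (coal_marginal(net, L.parent, L.agep, L.tip_sp, L.mgp, L.sc)) {
          double ldnew = marg_logdens(L.mgp, phi);
          if (R_FINITE(ldnew)) {
            L.path_dirty(v);
            double llnew = L.recompute_dirty(L.agep);
            double lr = (ldnew - L.logdens) + (llnew - L.loglik);
            if (lr >= 0 || unif_rand() < std::exp(lr)) {
              L.age[v] = prop;
              L.commit_dirty();
              L.loglik = llnew; L.logdens = ldnew;
              std::swap(L.mg, L.mgp);
              accept = true;
            }
          }
        }
        (void)old;
        t_age.hit(accept);
      }

      { // NNI around a random internal non-root edge
        int r = L.root();
        if (L.nn - L.nt > 1) {
          int v;
          do { v = L.nt + (int)(unif_rand() * (L.nn - L.nt)); } while (v == r);
          int u = L.parent[v];
          int w = (L.ch[u][0] == v) ? L.ch[u][1] : L.ch[u][0];
          int cidx = (unif_rand() < 0.5) ? 0 : 1;
          int x = L.ch[v][cidx];
          bool accept = false;
          if (L.age[w] < L.age[v]) {
            L.parent[w] = v; L.parent[x] = u;
            for (int j = 0; j < 2; j++) {
              if (L.ch[u][j] == w) L.ch[u][j] = x;
              if (L.ch[v][j] == x) L.ch[v][j] = w;
            }
            if (coal_marginal(net, L.parent, L.age, L.tip_sp, L.mgp, L.sc)) {
              double ldnew = marg_logdens(L.mgp, phi);
              if (R_FINITE(ldnew)) {
                L.path_dirty(v);
                double llnew = L.recompute_dirty(L.age);
                double lr = (ldnew - L.logdens) + (llnew - L.loglik);
                if (lr >= 0 || unif_rand() < std::exp(lr)) {
                  L.commit_dirty();
                  L.loglik = llnew; L.logdens = ldnew;
                  std::swap(L.mg, L.mgp);
                  accept = true;
                }
              }
            }
            if (!accept) {
              L.parent[w] = u; L.parent[x] = v;
              for (int j = 0; j < 2; j++) {
                if (L.ch[u][j] == x) L.ch[u][j] = w;
                if (L.ch[v][j] == w) L.ch[v][j] = x;
              }
            }
          }
          t_nni.hit(accept);
        }
      }

      if (resim_every > 0 && iter % resim_every == 0)
      { // independence proposal: resimulate the locus gene tree from the
        // coalescent prior at the current parameters; the prior densities
        // cancel, leaving the sequence-likelihood ratio.  Dramatically
        // improves mixing when the per-locus data are weak.  The simulator
        // creates internal nodes in age order (tips 0..nt-1, then
        // coalescences oldest-last), so index order is a valid postorder and
        // the proposal likelihood is computed in one pass into clvp; on
        // acceptance the buffers are swapped.
        L.tip_pops.resize(L.nt);
        for (int i = 0; i < L.nt; i++)
          L.tip_pops[i] = net.pop_at(L.tip_sp[i], 0.0);
        int nj;
        sim_core(net, L.tip_pops, L.parentp, L.agep2, nj);
        double llnew = 0.0;
        {
          // children of the proposed tree (child index < parent index)
          std::vector<int>& c1 = L.sc.c1v; std::vector<int>& c2 = L.sc.c2v;
          c1.assign(L.nn, -1); c2.assign(L.nn, -1);
          for (int i = 0; i < L.nn; i++) {
            int p = L.parentp[i];
            if (p < 0) continue;
            if (c1[p] < 0) c1[p] = i; else c2[p] = i;
          }
          for (int v = 0; v < L.nn; v++) {
            double* cv = &L.clvp[(size_t)v * L.npat * 4];
            if (v < L.nt) {
              for (int s = 0; s < L.npat; s++) {
                int m = L.mask[(size_t)s * L.nt + v];
                for (int x = 0; x < 4; x++) cv[s*4+x] = (m >> x) & 1 ? 1.0 : 0.0;
              }
              continue;
            }
            const int cc[2] = {c1[v], c2[v]};
            for (int s = 0; s < L.npat * 4; s++) cv[s] = 1.0;
            for (int j = 0; j < 2; j++) {
              const double* cvc = &L.clvp[(size_t)cc[j] * L.npat * 4];
              double e = std::exp(-4.0 * (L.agep2[v] - L.agep2[cc[j]]) / 3.0);
              for (int s = 0; s < L.npat; s++) {
                double S = cvc[s*4] + cvc[s*4+1] + cvc[s*4+2] + cvc[s*4+3];
                for (int x = 0; x < 4; x++)
                  cv[s*4+x] *= 0.25*S + e * (cvc[s*4+x] - 0.25*S);
              }
            }
          }
          const double* rv = &L.clvp[(size_t)(L.nn - 1) * L.npat * 4];
          for (int s = 0; s < L.npat; s++)
            llnew += L.wt[s] * std::log(0.25 * (rv[s*4] + rv[s*4+1] +
                                                rv[s*4+2] + rv[s*4+3]));
        }
        double lr = llnew - L.loglik;
        bool accept = false;
        if (R_FINITE(llnew) && (lr >= 0 || unif_rand() < std::exp(lr))) {
          if (coal_marginal(net, L.parentp, L.agep2, L.tip_sp, L.mgp, L.sc)) {
            std::swap(L.parent, L.parentp);
            std::swap(L.age, L.agep2);
            L.rebuild_children();
            std::swap(L.clv, L.clvp);
            L.loglik = llnew;
            std::swap(L.mg, L.mgp);
            L.logdens = marg_logdens(L.mg, phi);
            accept = true;
          }
        }
        t_resim.hit(accept);
      }
    }

    // ----- phi: partially collapsed Gibbs (draw assignments, then phi) -----
    if (net.has_hybrid) {
      long A = 0, B = 0;
      for (int l = 0; l < nloci; l++) {
        int b = marg_draw(loci[l].mg, phi);
        A += loci[l].mg.acnt[b];
        B += loci[l].mg.k - loci[l].mg.acnt[b];
      }
      phi = R::rbeta(a_ph + A, b_ph + B);
      phi = std::min(std::max(phi, 1e-12), 1.0 - 1e-12);
      net.phi = phi;
      for (int l = 0; l < nloci; l++)
        loci[l].logdens = marg_logdens(loci[l].mg, phi);
    }

    // ----- theta: MH on log scale using cached per-assignment statistics ----
    for (int j = 0; j < net.nsp; j++) {
      double th = net.theta[j];
      double thp = th * std::exp((unif_rand()*2 - 1) * t_th.step);
      double dlog = std::log(thp) - std::log(th);
      double dinv = 1.0/thp - 1.0/th;
      double lr = a_th * dlog - b_th * (thp - th); // prior + proposal Jacobian
      std::vector<double> newld(nloci);
      for (int l = 0; l < nloci; l++) {
        Marg& m = loci[l].mg;
        // adjust logw per assignment, then re-marginalise
        double lphi = (phi > 0) ? std::log(phi) : R_NegInf;
        double l1m  = (phi < 1) ? std::log1p(-phi) : R_NegInf;
        double mx = R_NegInf;
        std::vector<double> v(m.nass, R_NegInf);
        for (int b = 0; b < m.nass; b++) {
          if (!m.valid[b]) continue;
          double d = 0.0;
          for (int p = 0; p < npop; p++) {
            if (net.pops[p].theta_idx != j) continue;
            d += -m.Cp[(size_t)b*npop + p] * dlog
                 - m.Sp[(size_t)b*npop + p] * dinv;
          }
          double x = m.logw[b] + d;
          if (m.acnt[b] > 0) x += m.acnt[b] * lphi;
          if (m.k - m.acnt[b] > 0) x += (m.k - m.acnt[b]) * l1m;
          v[b] = x;
          if (x > mx) mx = x;
        }
        double s = 0.0;
        for (int b = 0; b < m.nass; b++)
          if (R_FINITE(v[b])) s += std::exp(v[b] - mx);
        newld[l] = R_FINITE(mx) ? mx + std::log(s) : R_NegInf;
        lr += newld[l] - loci[l].logdens;
      }
      bool accept = R_FINITE(lr) && (lr >= 0 || unif_rand() < std::exp(lr));
      if (accept) {
        for (int l = 0; l < nloci; l++) {
          Marg& m = loci[l].mg;
          for (int b = 0; b < m.nass; b++) {
            if (!m.valid[b]) continue;
            double d = 0.0;
            for (int p = 0; p < npop; p++) {
              if (net.pops[p].theta_idx != j) continue;
              d += -m.Cp[(size_t)b*npop + p] * dlog
                   - m.Sp[(size_t)b*npop + p] * dinv;
            }
            m.logw[b] += d;
          }
          loci[l].logdens = newld[l];
        }
        net.theta[j] = thp;
        net.build();
      }
      t_th.hit(accept);
    }

    // ----- mixing move: rescale all times and population sizes jointly ----
    // x' = c x for every free tau (incl. the introgression time), every
    // theta, and every gene-tree node age.  The coalescent core transforms
    // analytically (each of the nt-1 coalescences contributes -log c; the
    // exposures are scale-invariant), so only the sequence likelihood needs
    // recomputation.  This travels along the tau-theta ridges that
    // single-parameter windows cross slowly.
    if (mix_every > 0 && iter % mix_every == 0) {
      double z = (unif_rand() * 2 - 1) * t_mix.step;
      double c = std::exp(z);
      double lc = std::log(c);
      long n_scaled = ntaup + net.nsp;
      double lr = 0.0;
      // gamma priors on thetas and the root age; flat taus keep their
      // ordering under a common scale
      for (int j = 0; j < net.nsp; j++)
        lr += (a_th - 1.0) * lc - b_th * (c - 1.0) * net.theta[j];
      lr += (a_ta - 1.0) * lc - b_ta * (c - 1.0) * net.sp_age[root_sp];
      lr += -k_free * lc;
      std::vector<double> llnews(nloci);
      for (int l = 0; l < nloci; l++) {
        Locus& L = loci[l];
        n_scaled += L.nn - L.nt;
        L.agep = L.age;
        for (int i = L.nt; i < L.nn; i++) L.agep[i] *= c;
        L.dirty.resize(L.nn);
        for (int i = 0; i < L.nn; i++) L.dirty[i] = i;
        std::sort(L.dirty.begin(), L.dirty.end(),
                  [&](int a, int b){ return L.agep[a] < L.agep[b]; });
        llnews[l] = L.recompute_dirty(L.agep);
        lr += llnews[l] - L.loglik - (L.nn - L.nt) * lc;
      }
      lr += n_scaled * lc; // multiplier-proposal Jacobian
      bool accept = R_FINITE(lr) && (lr >= 0 || unif_rand() < std::exp(lr));
      if (accept) {
        for (int j = 0; j < net.nsp; j++) net.theta[j] *= c;
        for (int v = 0; v < net.nsp; v++) net.sp_age[v] *= c;
        if (net.has_hybrid) net.tau_h *= c;
        net.build();
        for (int l = 0; l < nloci; l++) {
          Locus& L = loci[l];
          L.age = L.agep;
          L.commit_dirty();
          L.loglik = llnews[l];
          for (int b = 0; b < L.mg.nass; b++) {
            if (!L.mg.valid[b]) continue;
            L.mg.logw[b] -= (L.nn - L.nt) * lc;
          }
          for (size_t q = 0; q < L.mg.Sp.size(); q++) L.mg.Sp[q] *= c;
          L.logdens -= (L.nn - L.nt) * lc;
        }
      }
      t_mix.hit(accept);
    }

    // ----- tau: rubber-band moves, conditioned on a drawn assignment -----
    // The last sweep slot (hybrid models only) is a coupled (tau_h, phi)
    // move along their posterior ridge: moving the introgression time
    // rescales phi so that the expected number of completed introgressions
    // (phi times the probability that an introgressed lineage coalesces in
    // the donor population, 1 - exp(-2 (hi_donor - tau_h)/theta_donor))
    // stays constant, with the exact Jacobian of the phi map.
    if (tau_every > 0 && iter % tau_every == 0) {
      int nmoves_tau = ntaup + (net.has_hybrid ? 3 : 0);
      for (int m_i = 0; m_i < nmoves_tau; m_i++) {
        bool coupled = net.has_hybrid && (m_i >= ntaup);
        int m_param = coupled ? ntau : m_i;
        bool is_tauh = (m_param >= ntau);
        int v = is_tauh ? -1 : tau_nodes[m_param];
        double told = is_tauh ? net.tau_h : net.sp_age[v];
        double lo = 0.0, hi = Inf;
        if (is_tauh) {
          lo = std::max(net.sp_age[net.rec], net.sp_age[net.donor]);
          double h1 = net.sp_parent[net.rec] < 0 ? Inf : net.sp_age[net.sp_parent[net.rec]];
          double h2 = net.sp_parent[net.donor] < 0 ? Inf : net.sp_age[net.sp_parent[net.donor]];
          hi = std::min(h1, h2);
        } else {
          for (int c = 0; c < net.nsp; c++)
            if (net.sp_parent[c] == v) lo = std::max(lo, net.sp_age[c]);
          if (net.has_hybrid &&
              (net.sp_parent[net.rec] == v || net.sp_parent[net.donor] == v))
            lo = std::max(lo, net.tau_h);
          if (net.has_hybrid && (v == net.rec || v == net.donor))
            hi = std::min(hi, net.tau_h);
          if (net.sp_parent[v] >= 0)
            hi = std::min(hi, net.sp_age[net.sp_parent[v]]);
        }
        if (!(hi > lo)) continue;
        // coupled moves mix window steps with occasional uniform jumps over
        // the whole support (both proposals are symmetric)
        double tnew = (coupled && unif_rand() < 0.3)
          ? lo + unif_rand() * (hi - lo)
          : reflect(told + (unif_rand()*2 - 1) * t_tau[m_i].step, lo, hi);
        if (tnew == told) continue;

        double lpr = 0.0;
        bool is_root = (!is_tauh && v == root_sp);
        if (is_root) {
          lpr += (a_ta - 1.0)*(std::log(tnew) - std::log(told)) - b_ta*(tnew - told);
          lpr += -k_free * (std::log(tnew) - std::log(told));
        }

        // coupled move: map phi along the completion-probability ridge
        double phinew = phi, dlp1 = 0.0, dlp0 = 0.0;
        if (coupled) {
          double hi_d = net.pops[net.hy_donor].hi;
          double th_d = net.theta[net.pops[net.hy_donor].theta_idx];
          if (R_FINITE(hi_d)) {
            double gold = -std::expm1(-2.0 * (hi_d - told) / th_d);
            double gnew = -std::expm1(-2.0 * (hi_d - tnew) / th_d);
            if (!(gnew > 0) || !(gold > 0)) { t_tau[m_i].hit(false); continue; }
            phinew = phi * gold / gnew;
            if (phinew >= 1.0 - 1e-9 || phinew <= 1e-12) {
              t_tau[m_i].hit(false); continue;
            }
            lpr += std::log(gold) - std::log(gnew); // Jacobian of the phi map
            lpr += (a_ph - 1.0) * (std::log(phinew) - std::log(phi))
                 + (b_ph - 1.0) * (std::log1p(-phinew) - std::log1p(-phi));
            dlp1 = std::log(phinew) - std::log(phi);
            dlp0 = std::log1p(-phinew) - std::log1p(-phi);
          }
        }

        Net netp = net;
        if (is_tauh) netp.tau_h = tnew; else netp.sp_age[v] = tnew;
        netp.phi = phinew;
        netp.build();

        double lsum = lpr;
        bool feasible = true;
        std::vector<int> draw(nloci);
        std::vector<std::vector<double> > agesp(nloci);
        std::vector<std::vector<int> > dirties(nloci);
        std::vector<double> lliks(nloci), lwnew(nloci), lwold(nloci);
        for (int l = 0; l < nloci && feasible; l++) {
          Locus& L = loci[l];
          int b = marg_draw(L.mg, phi);
          draw[l] = b;
          if (coupled)
            lsum += L.mg.acnt[b] * dlp1 + (L.mg.k - L.mg.acnt[b]) * dlp0;
          const int* npb = &L.mg.node_pop[(size_t)b * L.nn];
          std::vector<double> na = L.age;
          double ljac = 0.0;
          std::vector<int> changed;
          for (int i = L.nt; i < L.nn; i++) {
            int p = npb[i];
            const Pop& P = net.pops[p];
            double a = L.age[i], a2 = a;
            if (P.hi_param == m_param) {
              double s = (tnew - P.lo) / (told - P.lo);
              a2 = P.lo + (a - P.lo) * s;
              ljac += std::log(s);
            } else if (P.lo_param == m_param) {
              if (R_FINITE(P.hi)) {
                double s = (P.hi - tnew) / (P.hi - told);
                a2 = P.hi - (P.hi - a) * s;
                ljac += std::log(s);
              } else {
                a2 = a + (tnew - told);
              }
            }
            na[i] = a2;
          }
          for (int i = 0; i < L.nn; i++)
            if (na[i] != L.age[i]) changed.push_back(i);
          // conditional coalescent core under assignment b, old and new
          std::vector<int> bits(L.nn, 0);
          for (int q = 0; q < L.mg.k; q++)
            bits[L.mg.cross[q]] = (b >> q) & 1;
          L.sc.prepare(L.parent, na);
          if (!coal_sweep(netp, L.parent, na, bits, L.tip_sp, L.sc) ||
              !R_FINITE(L.sc.logw)) { feasible = false; break; }
          lwnew[l] = L.sc.logw;
          lwold[l] = L.mg.logw[b];
          double llnew = L.loglik;
          if (!changed.empty()) {
            std::vector<char> isd(L.nn, 0);
            for (size_t q = 0; q < changed.size(); q++) {
              int x = changed[q];
              while (x >= 0 && !isd[x]) { isd[x] = 1; x = L.parent[x]; }
              int pp = L.parent[changed[q]];
              while (pp >= 0 && !isd[pp]) { isd[pp] = 1; pp = L.parent[pp]; }
            }
            L.dirty.clear();
            for (int i = 0; i < L.nn; i++) if (isd[i]) L.dirty.push_back(i);
            std::sort(L.dirty.begin(), L.dirty.end(),
                      [&](int aa, int bb){ return na[aa] < na[bb]; });
            llnew = L.recompute_dirty(na);
            if (!R_FINITE(llnew)) { feasible = false; break; }
            dirties[l] = L.dirty;
          }
          lsum += ljac + (lwnew[l] - lwold[l]) + (llnew - L.loglik);
          agesp[l] = na; lliks[l] = llnew;
        }
        bool accept = feasible && (lsum >= 0 || unif_rand() < std::exp(lsum));
        if (accept) {
          for (int l = 0; l < nloci; l++) {
            Locus& L = loci[l];
            L.age = agesp[l];
            if (!dirties[l].empty()) {
              L.dirty = dirties[l];
              L.commit_dirty();
            }
            L.loglik = lliks[l];
          }
          net = netp;
          if (coupled) phi = phinew;
          // refresh the marginal caches under the new network
          for (int l = 0; l < nloci; l++) {
            Locus& L = loci[l];
            if (!coal_marginal(net, L.parent, L.age, L.tip_sp, L.mg, L.sc))
              stop("internal error: accepted tau move left an incompatible state");
            L.logdens = marg_logdens(L.mg, phi);
          }
        }
        t_tau[m_i].hit(accept);
      }
    }

    if (adapt && iter % 50 == 49) {
      t_age.adapt(); t_th.adapt(); t_mix.adapt();
      for (size_t m_i = 0; m_i < t_tau.size(); m_i++) t_tau[m_i].adapt();
    }

    if (iter >= burnin && (iter - burnin) % thin == 0 && srow < nsamp) {
      int col = 0;
      for (int m_i = 0; m_i < ntau; m_i++) trace(srow, col++) = net.sp_age[tau_nodes[m_i]];
      if (net.has_hybrid) trace(srow, col++) = net.tau_h;
      for (int j = 0; j < net.nsp; j++) trace(srow, col++) = net.theta[j];
      if (net.has_hybrid) trace(srow, col++) = phi;
      double lltot = 0.0;
      for (int l = 0; l < nloci; l++) lltot += loci[l].loglik;
      trace(srow, col++) = lltot;
      srow++;
    }
  }

  CharacterVector cn(trace.ncol());
  int col = 0;
  for (int m_i = 0; m_i < ntau; m_i++)
    cn[col++] = "tau_" + std::to_string(tau_nodes[m_i]);
  if (net.has_hybrid) cn[col++] = "tau_h";
  for (int j = 0; j < net.nsp; j++)
    cn[col++] = "theta_" + std::to_string(j);
  if (net.has_hybrid) cn[col++] = "phi";
  cn[col++] = "lnL";
  colnames(trace) = cn;

  double mean_tau_rate = NA_REAL;
  if (!t_tau.empty()) {
    mean_tau_rate = 0.0;
    for (size_t m_i = 0; m_i < t_tau.size(); m_i++)
      mean_tau_rate += t_tau[m_i].rate();
    mean_tau_rate /= t_tau.size();
  }
  NumericVector acc = NumericVector::create(
    _["age"] = t_age.rate(), _["nni"] = t_nni.rate(),
    _["resim"] = t_resim.rate(), _["mix"] = t_mix.rate(),
    _["theta"] = t_th.rate(), _["tau"] = mean_tau_rate);
  return List::create(_["trace"] = trace, _["acceptance"] = acc);
}
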