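// Exact continuous-time Monte Carlo (Gillespie) engine for site-graph
// scission models.
//
// Site compatibility is a fixed template: every possible bond realizes one
// of the model's compatible site pairs, so the engine keeps one propensity
// slot per realizable pair — concrete growth-growth pairs, one pooled slot
// per cut-slat pair template (rate k_on_inter x free copies), and one slot
// per pair of each *active* (ribbon-engaged) cut-slat instance — in a binary
// sum tree. A slot's rate depends only on local state (occupancy of its two
// sites, bond degree of their owner slats, pool counts), so each event
// refreshes O(local) slots.
//
// The three-point locality constraint on intracomplex binds is enforced by
// thinning: a same-complex candidate pair carries the full k_on_intra as an
// upper bound, and a breadth-first search over at most three bonds decides
// acceptance when the candidate fires; a rejected firing is a null event
// whose waiting time still elapses. Because the true intensity is either
// the bound or zero and the state is frozen between events, the sampled
// process is exact. Locality over <= 3 bonds implies membership in one
// complex, so the constraint also excludes complex-complex joining without
// any global connectivity bookkeeping; connected components are tracked
// only for the observables (complex sizes, half-bridging).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

namespace {

struct Comp {
  int size = 0;       // slats in the complex
  int nA = 0, nB = 0; // growth slats of each ribbon half
  bool alive = false;
};

struct Engine {
  // ---- static model ----
  int nT = 0;
  std::vector<int> tGrowth, tCopies, tHalf, tNsites;
  int nTS = 0;
  std::vector<int> tsOwner, tsLocal;
  int nP = 0;
  std::vector<int> pI, pJ, pGG, pWob, pToe;
  std::vector<int> pCutType, pCutSite, pGrowthSite;
  double k_off = 1, k_on_inter = 0.04, k_on_intra = 40, wob_on = 1, wob_off = 1;
  bool recycleGrowth = true;

  // ---- instances ----
  int nI = 0, nIS = 0;
  std::vector<int> iType, iCopy, isBase, isOwner, growthInst;
  std::vector<int> partner, bondPair, deg;
  std::vector<char> active, removed;
  std::vector<std::vector<int>> freeStack;
  std::vector<int> freeCount;

  // ---- slots ----
  int nGG = 0, nCP = 0, dynBase = 0, nSlots = 0;
  std::vector<int> ggPair, cpPair;
  std::vector<int> typePairStart, typePairs, instDynBase;
  std::vector<int> slotPair, slotA, slotB, slotKind, slotInst, slotPoolType;
  std::vector<std::vector<int>> siteStaticSlots, siteActiveSlots;
  std::vector<std::vector<int>> poolSlotsOfType;

  // ---- sum tree ----
  int treeN = 1;
  std::vector<double> tree;

  // ---- complexes ----
  std::vector<int> compId;
  std::vector<Comp> comps;
  std::vector<int> compFree;
  int nComplex = 0, nBridging = 0;

  // ---- scratch ----
  std::vector<int> stamp, bfsQueue;
  int stampCtr = 0;

  // ------------------------------------------------------------------
  int isiteOf(int inst, int ts) const { return isBase[inst] + tsLocal[ts]; }

  double pairRate(int p, int a, int b) const {
    if (partner[a] == b) return k_off * (pWob[p] ? wob_off : 1.0);
    if (partner[a] >= 0 || partner[b] >= 0) return 0.0;
    int oa = isOwner[a], ob = isOwner[b];
    if (removed[oa] || removed[ob]) return 0.0;
    int da = deg[oa], db = deg[ob];
    if (da == 0 && db == 0) return 0.0; // two free monomers never join
    double won = pWob[p] ? wob_on : 1.0;
    if (da == 0 || db == 0) return k_on_inter * won;
    return k_on_intra * won; // upper bound; locality decided on firing
  }

  double slotRate(int s) const {
    int k = slotKind[s];
    if (k == 1) { // pooled: free copies of a cut type vs a ribbon site
      int t = slotPoolType[s], g = slotB[s];
      if (freeCount[t] == 0 || partner[g] >= 0) return 0.0;
      int og = isOwner[g];
      if (removed[og] || deg[og] == 0) return 0.0;
      return k_on_inter * freeCount[t];
    }
    if (k == 2 && !active[slotInst[s]]) return 0.0;
    return pairRate(slotPair[s], slotA[s], slotB[s]);
  }

  void treeSet(int s, double v) {
    int i = treeN + s;
    if (tree[i] == v) return;
    tree[i] = v;
    for (i >>= 1; i >= 1; i >>= 1) tree[i] = tree[2 * i] + tree[2 * i + 1];
  }
  double total() const { return tree[1]; }
  int treeSelect(double u) const {
    int i = 1;
    while (i < treeN) {
      i <<= 1;
      if (u >= tree[i] && tree[i + 1] > 0.0) { u -= tree[i]; ++i; }
    }
    return i - treeN;
  }

  void refreshSlot(int s) { treeSet(s, slotRate(s)); }
  void refreshSite(int g) {
    for (int s : siteStaticSlots[g]) refreshSlot(s);
    for (int s : siteActiveSlots[g]) refreshSlot(s);
  }
  void refreshInstanceDyn(int inst) {
    int t = iType[inst];
    int np = typePairStart[t + 1] - typePairStart[t];
    for (int k = 0; k < np; ++k) refreshSlot(instDynBase[inst] + k);
  }
  void refreshSiteOrInst(int is) {
    int o = isOwner[is];
    if (tGrowth[iType[o]]) refreshSite(is);
    else refreshInstanceDyn(o);
  }
  void refreshOwnerAllSites(int inst) {
    if (tGrowth[iType[inst]]) {
      for (int k = 0; k < tNsites[iType[inst]]; ++k) refreshSite(isBase[inst] + k);
    } else {
      refreshInstanceDyn(inst);
    }
  }
  void refreshTypePool(int t) {
    for (int s : poolSlotsOfType[t]) refreshSlot(s);
  }

  // ---- graph searches -------------------------------------------------
  bool within3(int a, int b) {
    if (a == b) return true;
    ++stampCtr;
    stamp[a] = stampCtr;
    bfsQueue.clear(); bfsQueue.push_back(a);
    size_t head = 0;
    int depth = 0;
    while (head < bfsQueue.size() && depth < 3) {
      ++depth;
      size_t stop_ = bfsQueue.size();
      for (; head < stop_; ++head) {
        int u = bfsQueue[head];
        int base = isBase[u], ns = tNsites[iType[u]];
        for (int k = 0; k < ns; ++k) {
          int pr = partner[base + k];
          if (pr < 0) continue;
          int v = isOwner[pr];
          if (v == b) return true;
          if (stamp[v] != stampCtr) { stamp[v] = stampCtr; bfsQueue.push_back(v); }
        }
      }
    }
    return false;
  }

  // full BFS from a; true if b reached, else bfsQueue holds a's component
  bool connected(int a, int b) {
    ++stampCtr;
    stamp[a] = stampCtr;
    bfsQueue.clear(); bfsQueue.push_back(a);
    for (size_t head = 0; head < bfsQueue.size(); ++head) {
      int u = bfsQueue[head];
      int base = isBase[u], ns = tNsites[iType[u]];
      for (int k = 0; k < ns; ++k) {
        int pr = partner[base + k];
        if (pr < 0) continue;
        int v = isOwner[pr];
        if (v == b) return true;
        if (stamp[v] != stampCtr) { stamp[v] = stampCtr; bfsQueue.push_back(v); }
      }
    }
    return false;
  }

  // ---- complex bookkeeping --------------------------------------------
  int newComp() {
    int c;
    if (!compFree.empty()) { c = compFree.back(); compFree.pop_back(); comps[c] = Comp(); }
    else { c = (int)comps.size(); comps.push_back(Comp()); }
    comps[c].alive = true;
    ++nComplex;
    return c;
  }
  static bool bridges(const Comp& c) { return c.nA > 0 && c.nB > 0; }
  void addMember(int c, int inst, int delta) {
    bool was = bridges(comps[c]);
    comps[c].size += delta;
    int t = iType[inst];
    if (tGrowth[t]) {
      if (tHalf[t] == 0) comps[c].nA += delta;
      else if (tHalf[t] == 1) comps[c].nB += delta;
    }
    bool now = bridges(comps[c]);
    if (was != now) nBridging += now ? 1 : -1;
  }
  void compJoin(int inst, int other) {
    int c = compId[other];
    compId[inst] = c;
    addMember(c, inst, +1);
  }
  void compLeave(int inst) {
    int c = compId[inst];
    addMember(c, inst, -1);
    compId[inst] = -1;
    if (comps[c].size == 0) { comps[c].alive = false; --nComplex; compFree.push_back(c); }
  }
  void compSplit(int a, int b) {
    if (connected(a, b)) return;
    int cOld = compId[a];
    int cNew = newComp();
    for (int u : bfsQueue) {
      compId[u] = cNew;
      addMember(cOld, u, -1);
      addMember(cNew, u, +1);
    }
  }

  // ---- event application ----------------------------------------------
  int activateInstance(int t) {
    int inst = freeStack[t].back();
    freeStack[t].pop_back();
    --freeCount[t];
    active[inst] = 1;
    int np = typePairStart[t + 1] - typePairStart[t];
    for (int k = 0; k < np; ++k) {
      int s = instDynBase[inst] + k;
      siteActiveSlots[slotB[s]].push_back(s);
    }
    return inst;
  }
  void deactivateInstance(int inst) {
    int t = iType[inst];
    active[inst] = 0;
    int np = typePairStart[t + 1] - typePairStart[t];
    for (int k = 0; k < np; ++k) {
      int s = instDynBase[inst] + k;
      std::vector<int>& v = siteActiveSlots[slotB[s]];
      for (size_t m = 0; m < v.size(); ++m)
        if (v[m] == s) { v[m] = v.back(); v.pop_back(); break; }
      treeSet(s, 0.0);
    }
    freeStack[t].push_back(inst);
    ++freeCount[t];
    refreshTypePool(t);
  }

  void formBond(int p, int a, int b) {
    partner[a] = b; partner[b] = a;
    bondPair[a] = p; bondPair[b] = p;
    int oa = isOwner[a], ob = isOwner[b];
    int da0 = deg[oa]++, db0 = deg[ob]++;
    if (da0 == 0) compJoin(oa, ob);
    else if (db0 == 0) compJoin(ob, oa);
    refreshSiteOrInst(a); refreshSiteOrInst(b);
    if (da0 == 0) refreshOwnerAllSites(oa);
    if (db0 == 0) refreshOwnerAllSites(ob);
  }

  void breakBond(int a, int b) {
    partner[a] = -1; partner[b] = -1;
    bondPair[a] = -1; bondPair[b] = -1;
    int oa = isOwner[a], ob = isOwner[b];
    int da = --deg[oa], db = --deg[ob];
    if (da == 0 && db == 0) { compLeave(oa); compLeave(ob); }
    else if (da == 0) compLeave(oa);
    else if (db == 0) compLeave(ob);
    else compSplit(oa, ob);
    refreshSiteOrInst(a); refreshSiteOrInst(b);
    int owners[2] = {oa, ob};
    for (int w = 0; w < 2; ++w) {
      int o = owners[w];
      if (deg[o] > 0) continue;
      if (!tGrowth[iType[o]]) deactivateInstance(o);
      else if (!recycleGrowth) { removed[o] = 1; refreshOwnerAllSites(o); }
      else refreshOwnerAllSites(o); // growth monomer; may rebind at inter rates
    }
  }

  // ---- observables ------------------------------------------------------
  int largestComplex() const {
    int m = 0;
    for (const Comp& c : comps) if (c.alive && c.size > m) m = c.size;
    return m;
  }
  int trackedSize() const {
    int c = compId[0]; // first growth slat anchors the tracked complex
    return c >= 0 ? comps[c].size : 1;
  }

  // ---- audit ------------------------------------------------------------
  void audit(double tNow) {
    std::vector<int> d2(nI, 0);
    for (int is = 0; is < nIS; ++is) {
      int pr = partner[is];
      if (pr < 0) continue;
      if (partner[pr] != is) stop("audit: asymmetric bond at t=%f", tNow);
      ++d2[isOwner[is]];
    }
    for (int i = 0; i < nI; ++i)
      if (d2[i] != deg[i]) stop("audit: degree mismatch at t=%f", tNow);
    std::vector<int> act(nT, 0), rem(nT, 0);
    for (int i = 0; i < nI; ++i) {
      if (active[i]) ++act[iType[i]];
      if (removed[i]) ++rem[iType[i]];
    }
    for (int t = 0; t < nT; ++t) {
      if (tGrowth[t]) continue;
      if (act[t] + freeCount[t] != tCopies[t])
        stop("audit: copy conservation violated for type %d at t=%f", t + 1, tNow);
    }
    for (int s = 0; s < nSlots; ++s)
      if (tree[treeN + s] != slotRate(s))
        stop("audit: stale propensity slot %d at t=%f (full rebuild differs)", s, tNow);
    // complexes: fresh labeling must reproduce the maintained partition
    std::vector<char> seen(nI, 0);
    int nc = 0, nbr = 0;
    for (int i = 0; i < nI; ++i) {
      if (deg[i] == 0 || seen[i]) continue;
      ++stampCtr;
      bfsQueue.clear(); bfsQueue.push_back(i); stamp[i] = stampCtr;
      int a = 0, b = 0, sz = 0;
      for (size_t h = 0; h < bfsQueue.size(); ++h) {
        int u = bfsQueue[h];
        seen[u] = 1; ++sz;
        int tt = iType[u];
        if (tGrowth[tt]) { if (tHalf[tt] == 0) ++a; else if (tHalf[tt] == 1) ++b; }
        if (compId[u] != compId[i]) stop("audit: complex membership mismatch at t=%f", tNow);
        int base = isBase[u], ns = tNsites[tt];
        for (int k = 0; k < ns; ++k) {
          int pr = partner[base + k];
          if (pr < 0) continue;
          int v = isOwner[pr];
          if (stamp[v] != stampCtr) { stamp[v] = stampCtr; bfsQueue.push_back(v); }
        }
      }
      int c = compId[i];
      if (c < 0 || !comps[c].alive || comps[c].size != sz ||
          comps[c].nA != a || comps[c].nB != b)
        stop("audit: complex size/half counts mismatch at t=%f", tNow);
      if (a > 0 && b > 0) ++nbr;
      ++nc;
    }
    if (nc != nComplex || nbr != nBridging)
      stop("audit: complex/bridging count mismatch at t=%f", tNow);
  }
};

void buildEngine(Engine& E, const List& model, bool prebound, bool recycle) {
  E.tGrowth = as<std::vector<int>>(model["type_is_growth"]);
  E.tCopies = as<std::vector<int>>(model["type_copies"]);
  E.tHalf = as<std::vector<int>>(model["type_half"]);
  E.nT = (int)E.tGrowth.size();
  E.tsOwner = as<std::vector<int>>(model["tsite_owner"]);
  E.nTS = (int)E.tsOwner.size();
  E.pI = as<std::vector<int>>(model["pair_i"]);
  E.pJ = as<std::vector<int>>(model["pair_j"]);
  E.pGG = as<std::vector<int>>(model["pair_gg"]);
  E.pWob = as<std::vector<int>>(model["pair_wobble"]);
  E.pToe = as<std::vector<int>>(model["pair_toehold"]);
  E.nP = (int)E.pI.size();
  E.k_off = as<double>(model["k_off"]);
  E.k_on_inter = as<double>(model["k_on_inter"]);
  E.k_on_intra = as<double>(model["k_on_intra"]);
  E.wob_on = as<double>(model["wobble_on"]);
  E.wob_off = as<double>(model["wobble_off"]);
  E.recycleGrowth = recycle;

  E.tNsites.assign(E.nT, 0);
  E.tsLocal.assign(E.nTS, 0);
  for (int ts = 0; ts < E.nTS; ++ts) E.tsLocal[ts] = E.tNsites[E.tsOwner[ts]]++;

  E.pCutType.assign(E.nP, -1);
  E.pCutSite.assign(E.nP, -1);
  E.pGrowthSite.assign(E.nP, -1);
  for (int p = 0; p < E.nP; ++p) {
    int ti = E.tsOwner[E.pI[p]], tj = E.tsOwner[E.pJ[p]];
    if (!E.tGrowth[ti]) { E.pCutType[p] = ti; E.pCutSite[p] = E.pI[p]; E.pGrowthSite[p] = E.pJ[p]; }
    else if (!E.tGrowth[tj]) { E.pCutType[p] = tj; E.pCutSite[p] = E.pJ[p]; E.pGrowthSite[p] = E.pI[p]; }
  }

  // instances: one per growth type, tCopies per cut type
  E.growthInst.assign(E.nT, -1);
  for (int t = 0; t < E.nT; ++t) {
    int nc = E.tGrowth[t] ? 1 : E.tCopies[t];
    for (int m = 0; m < nc; ++m) {
      if (E.tGrowth[t]) E.growthInst[t] = (int)E.iType.size();
      E.iType.push_back(t);
      E.iCopy.push_back(m);
    }
  }
  E.nI = (int)E.iType.size();
  E.isBase.assign(E.nI, 0);
  int acc = 0;
  for (int i = 0; i < E.nI; ++i) { E.isBase[i] = acc; acc += E.tNsites[E.iType[i]]; }
  E.nIS = acc;
  E.isOwner.assign(E.nIS, 0);
  for (int i = 0; i < E.nI; ++i)
    for (int k = 0; k < E.tNsites[E.iType[i]]; ++k) E.isOwner[E.isBase[i] + k] = i;

  E.partner.assign(E.nIS, -1);
  E.bondPair.assign(E.nIS, -1);
  E.deg.assign(E.nI, 0);
  E.active.assign(E.nI, 0);
  E.removed.assign(E.nI, 0);
  E.compId.assign(E.nI, -1);
  E.stamp.assign(E.nI, 0);

  std::vector<std::vector<int>> tp(E.nT);
  for (int p = 0; p < E.nP; ++p)
    if (E.pCutType[p] >= 0) tp[E.pCutType[p]].push_back(p);
  E.typePairStart.assign(E.nT + 1, 0);
  for (int t = 0; t < E.nT; ++t)
    E.typePairStart[t + 1] = E.typePairStart[t] + (int)tp[t].size();
  for (int t = 0; t < E.nT; ++t)
    for (int p : tp[t]) E.typePairs.push_back(p);

  for (int p = 0; p < E.nP; ++p) {
    if (E.pGG[p]) E.ggPair.push_back(p);
    else E.cpPair.push_back(p);
  }
  E.nGG = (int)E.ggPair.size();
  E.nCP = (int)E.cpPair.size();
  E.dynBase = E.nGG + E.nCP;
  E.instDynBase.assign(E.nI, -1);
  int dyn = 0;
  for (int i = 0; i < E.nI; ++i) {
    int t = E.iType[i];
    if (E.tGrowth[t]) continue;
    E.instDynBase[i] = E.dynBase + dyn;
    dyn += (int)tp[t].size();
  }
  E.nSlots = E.dynBase + dyn;
  E.slotPair.assign(E.nSlots, -1);
  E.slotA.assign(E.nSlots, -1);
  E.slotB.assign(E.nSlots, -1);
  E.slotKind.assign(E.nSlots, 0);
  E.slotInst.assign(E.nSlots, -1);
  E.slotPoolType.assign(E.nSlots, -1);
  E.siteStaticSlots.assign(E.nIS, {});
  E.siteActiveSlots.assign(E.nIS, {});
  E.poolSlotsOfType.assign(E.nT, {});

  for (int s = 0; s < E.nGG; ++s) {
    int p = E.ggPair[s];
    int a = E.isiteOf(E.growthInst[E.tsOwner[E.pI[p]]], E.pI[p]);
    int b = E.isiteOf(E.growthInst[E.tsOwner[E.pJ[p]]], E.pJ[p]);
    E.slotPair[s] = p; E.slotA[s] = a; E.slotB[s] = b; E.slotKind[s] = 0;
    E.siteStaticSlots[a].push_back(s);
    E.siteStaticSlots[b].push_back(s);
  }
  for (int k = 0; k < E.nCP; ++k) {
    int s = E.nGG + k, p = E.cpPair[k];
    int g = E.isiteOf(E.growthInst[E.tsOwner[E.pGrowthSite[p]]], E.pGrowthSite[p]);
    E.slotPair[s] = p; E.slotB[s] = g; E.slotKind[s] = 1;
    E.slotPoolType[s] = E.pCutType[p];
    E.siteStaticSlots[g].push_back(s);
    E.poolSlotsOfType[E.pCutType[p]].push_back(s);
  }
  for (int i = 0; i < E.nI; ++i) {
    int t = E.iType[i];
    if (E.tGrowth[t]) continue;
    const std::vector<int>& lst = tp[t];
    for (size_t k = 0; k < lst.size(); ++k) {
      int s = E.instDynBase[i] + (int)k, p = lst[k];
      E.slotPair[s] = p;
      E.slotA[s] = E.isiteOf(i, E.pCutSite[p]);
      E.slotB[s] = E.isiteOf(E.growthInst[E.tsOwner[E.pGrowthSite[p]]], E.pGrowthSite[p]);
      E.slotKind[s] = 2;
      E.slotInst[s] = i;
    }
  }

  E.freeStack.assign(E.nT, {});
  E.freeCount.assign(E.nT, 0);
  for (int i = E.nI - 1; i >= 0; --i) {
    int t = E.iType[i];
    if (!E.tGrowth[t]) { E.freeStack[t].push_back(i); ++E.freeCount[t]; }
  }

  // intact ribbon: every growth-growth pair bonded
  for (int s = 0; s < E.nGG; ++s) {
    int p = E.ggPair[s], a = E.slotA[s], b = E.slotB[s];
    E.partner[a] = b; E.partner[b] = a;
    E.bondPair[a] = p; E.bondPair[b] = p;
    ++E.deg[E.isOwner[a]]; ++E.deg[E.isOwner[b]];
  }
  if (prebound) {
    // one copy of each cut type engages all its toeholds
    for (int t = 0; t < E.nT; ++t) {
      if (E.tGrowth[t] || E.freeCount[t] == 0) continue;
      bool hasToe = false;
      for (int k = E.typePairStart[t]; k < E.typePairStart[t + 1]; ++k)
        if (E.pToe[E.typePairs[k]]) { hasToe = true; break; }
      if (!hasToe) continue;
      int inst = E.activateInstance(t);
      for (int k = E.typePairStart[t]; k < E.typePairStart[t + 1]; ++k) {
        int p = E.typePairs[k];
        if (!E.pToe[p]) continue;
        int a = E.isiteOf(inst, E.pCutSite[p]);
        int g = E.isiteOf(E.growthInst[E.tsOwner[E.pGrowthSite[p]]], E.pGrowthSite[p]);
        if (E.partner[g] >= 0) stop("prebound init: extension host already occupied");
        E.partner[a] = g; E.partner[g] = a;
        E.bondPair[a] = p; E.bondPair[g] = p;
        ++E.deg[inst]; ++E.deg[E.isOwner[g]];
      }
    }
  }

  // initial complex labeling
  for (int i = 0; i < E.nI; ++i) {
    if (E.deg[i] == 0 || E.compId[i] >= 0) continue;
    int c = E.newComp();
    ++E.stampCtr;
    E.bfsQueue.clear(); E.bfsQueue.push_back(i); E.stamp[i] = E.stampCtr;
    for (size_t h = 0; h < E.bfsQueue.size(); ++h) {
      int u = E.bfsQueue[h];
      E.compId[u] = c;
      E.addMember(c, u, +1);
      int base = E.isBase[u], ns = E.tNsites[E.iType[u]];
      for (int k = 0; k < ns; ++k) {
        int pr = E.partner[base + k];
        if (pr < 0) continue;
        int v = E.isOwner[pr];
        if (E.stamp[v] != E.stampCtr) { E.stamp[v] = E.stampCtr; E.bfsQueue.push_back(v); }
      }
    }
  }

  E.treeN = 1;
  while (E.treeN < std::max(1, E.nSlots)) E.treeN <<= 1;
  E.tree.assign(2 * E.treeN, 0.0);
  for (int s = 0; s < E.nSlots; ++s) {
    double v = E.slotRate(s);
    if (v != 0.0) {
      E.tree[E.treeN + s] = v;
    }
  }
  for (int i = E.treeN - 1; i >= 1; --i) E.tree[i] = E.tree[2 * i] + E.tree[2 * i + 1];
}

} // namespace

// [[Rcpp::export]]
List ccr_run_cpp(List model, bool prebound, double t_max, double event_max,
                 bool stop_on_scission, bool log_events, int audit_interval,
                 bool recycle_growth) {
  Engine E;
  buildEngine(E, model, prebound, recycle_growth);
  double initial_total = E.total();

  std::vector<double> sT; std::vector<int> sTr, sNc, sLg, sBr;
  std::vector<double> evT; std::vector<int> evK, evA, evB;
  auto pushSample = [&](double t) {
    sT.push_back(t);
    sTr.push_back(E.trackedSize());
    sNc.push_back(E.nComplex);
    sLg.push_back(E.largestComplex());
    sBr.push_back(E.nBridging);
  };
  pushSample(0.0);

  double t = 0.0, nEvents = 0, nNull = 0;
  std::string termination = "t_max";
  if (stop_on_scission && E.nBridging == 0) termination = "scission";
  bool done = (termination == "scission");

  while (!done) {
    double tot = E.total();
    if (tot <= 0.0) { termination = "no_events"; break; }
    double tau = R::exp_rand() / tot;
    if (t + tau > t_max) { t = t_max; termination = "t_max"; break; }
    t += tau;
    double u = unif_rand() * tot;
    int s = E.treeSelect(u);
    if (s >= E.nSlots || E.tree[E.treeN + s] <= 0.0) { ++nNull; continue; }

    int kind, ia, ib;
    if (E.slotKind[s] == 1) { // pooled intercomplex bind: activate a free copy
      int p = E.slotPair[s];
      int inst = E.activateInstance(E.pCutType[p]);
      E.refreshTypePool(E.pCutType[p]);
      ia = E.isiteOf(inst, E.pCutSite[p]);
      ib = E.slotB[s];
      E.formBond(p, ia, ib);
      kind = 1;
    } else {
      ia = E.slotA[s]; ib = E.slotB[s];
      int p = E.slotPair[s];
      if (E.partner[ia] == ib) {
        kind = 3;
        E.breakBond(ia, ib);
      } else {
        int oa = E.isOwner[ia], ob = E.isOwner[ib];
        if (E.deg[oa] > 0 && E.deg[ob] > 0) {
          if (!E.within3(oa, ob)) { ++nNull; continue; } // thinning null event
          kind = 2;
        } else {
          kind = 1;
        }
        E.formBond(p, ia, ib);
      }
    }
    nEvents += 1;
    if (log_events) {
      evT.push_back(t); evK.push_back(kind);
      evA.push_back(ia + 1); evB.push_back(ib + 1);
    }
    if (audit_interval > 0 && ((long long)nEvents % audit_interval) == 0)
      E.audit(t);

    int tr = E.trackedSize(), lg = E.largestComplex();
    if (tr != sTr.back() || lg != sLg.back() ||
        E.nComplex != sNc.back() || E.nBridging != sBr.back())
      pushSample(t);

    if (stop_on_scission && E.nBridging == 0) { termination = "scission"; done = true; }
    else if (nEvents >= event_max) { termination = "event_max"; done = true; }
  }
  if (audit_interval > 0) E.audit(t);
  if (sT.back() != t) pushSample(t);

  // final bonds and complex table
  std::vector<int> fbA, fbB;
  for (int is = 0; is < E.nIS; ++is)
    if (E.partner[is] > is) { fbA.push_back(is + 1); fbB.push_back(E.partner[is] + 1); }
  std::vector<int> fcSize, fcA, fcB;
  for (const Comp& c : E.comps)
    if (c.alive) { fcSize.push_back(c.size); fcA.push_back(c.nA); fcB.push_back(c.nB); }

  // instance -> (type, copy) and isite -> (instance, template site)
  IntegerVector instType(E.nI), instCopy(E.nI);
  for (int i = 0; i < E.nI; ++i) { instType[i] = E.iType[i] + 1; instCopy[i] = E.iCopy[i] + 1; }
  IntegerVector isInst(E.nIS), isTsite(E.nIS);
  for (int is = 0; is < E.nIS; ++is) {
    int o = E.isOwner[is];
    isInst[is] = o + 1;
    // template site: the tsLocal-th site of the owner's type
    isTsite[is] = 0;
  }
  // recover template-site ids: sites of a type appear in template order
  {
    std::vector<std::vector<int>> sitesOfType(E.nT);
    for (int ts = 0; ts < E.nTS; ++ts) sitesOfType[E.tsOwner[ts]].push_back(ts);
    for (int i = 0; i < E.nI; ++i) {
      const std::vector<int>& st = sitesOfType[E.iType[i]];
      for (size_t k = 0; k < st.size(); ++k) isTsite[E.isBase[i] + (int)k] = st[k] + 1;
    }
  }

  return List::create(
    _["samples"] = DataFrame::create(
        _["time"] = sT, _["tracked_complex_size"] = sTr,
        _["n_complexes"] = sNc, _["largest_complex_size"] = sLg,
        _["bridging"] = sBr),
    _["events"] = log_events ? (SEXP)DataFrame::create(
        _["time"] = evT, _["kind"] = evK,
        _["isite_i"] = evA, _["isite_j"] = evB) : R_NilValue,
    _["termination"] = termination,
    _["t_end"] = t,
    _["n_events"] = nEvents,
    _["n_null"] = nNull,
    _["initial_total_propensity"] = initial_total,
    _["final_bonds"] = DataFrame::create(_["isite_i"] = fbA, _["isite_j"] = fbB),
    _["final_complexes"] = DataFrame::create(
        _["size"] = fcSize, _["growth_a"] = fcA, _["growth_b"] = fcB),
    _["pool"] = IntegerVector(E.freeCount.begin(), E.freeCount.end()),
    _["inst_type"] = instType,
    _["inst_copy"] = instCopy,
    _["isite_inst"] = isInst,
    _["isite_tsite"] = isTsite);
}

// Initial candidate set with locality fully resolved (for cross-checking
// against the reference enumeration). Pooled candidates are reported with
// their aggregate propensity (k_on_inter x free copies).
// [[Rcpp::export]]
List ccr_candidates_cpp(List model, bool prebound, bool recycle_growth) {
  Engine E;
  buildEngine(E, model, prebound, recycle_growth);
  std::vector<int> pair, kind;
  std::vector<double> prop;
  for (int s = 0; s < E.nSlots; ++s) {
    double v = E.slotRate(s);
    if (v <= 0.0) continue;
    int k;
    if (E.slotKind[s] == 1) k = 1;
    else if (E.partner[E.slotA[s]] == E.slotB[s]) k = 3;
    else {
      int oa = E.isOwner[E.slotA[s]], ob = E.isOwner[E.slotB[s]];
      if (E.deg[oa] > 0 && E.deg[ob] > 0) {
        if (!E.within3(oa, ob)) continue; // not a true candidate
        k = 2;
      } else k = 1;
    }
    pair.push_back(E.slotPair[s] + 1);
    kind.push_back(k);
    prop.push_back(v);
  }
  return List::create(
    _["pair"] = pair, _["kind"] = kind, _["propensity"] = prop,
    _["total"] = std::accumulate(prop.begin(), prop.end(), 0.0));
}
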