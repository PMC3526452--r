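// Maximum-weight matching in general graphs (primal-dual blossom method,
// Galil 1986 formulation: O(V^3) worst case, much faster on sparse inputs).
// Computes a matching of maximum total weight -- NOT maximum cardinality:
// with positive weights an edge is only matched if it pays for itself.
//
// Dual variables are stored doubled (dualvar[v] = 2*u(v)) so that with
// integer edge weights all duals remain dyadic rationals, which IEEE
// doubles represent exactly; callers wanting exact arithmetic pre-scale
// rational weights to integers.

#include <Rcpp.h>
#include <cstdlib>
#include <deque>
#include <unordered_map>
#include <vector>

namespace {

const int LBL_NONE = 0, LBL_S = 1, LBL_T = 2, LBL_CRUMB = 4;
const int NOVERT = -1;

struct Matcher {
  bool dbg = false;
  int n;                    // number of vertices (0..n-1); blossom ids n..2n-1
  int m;                    // number of edges
  std::vector<int> ei, ej;  // edge endpoints
  std::vector<double> ew;   // edge weights
  std::vector<std::vector<int>> adj;  // incident edge ids per vertex
  std::unordered_map<long long, int> eid;  // (min,max) packed -> edge id

  std::vector<int> mate;          // mate[v] = matched vertex or -1
  std::vector<int> label;         // per blossom id (0..2n-1)
  std::vector<std::pair<int, int>> labeledge;  // (v,w), w inside the blossom
  std::vector<int> inblossom;     // top-level blossom of each vertex
  std::vector<int> blossomparent; // -1 = top level / unused
  std::vector<int> blossombase;
  std::vector<std::vector<int>> blossomchilds;
  std::vector<std::vector<std::pair<int, int>>> blossomedges;
  std::vector<char> blossomused;  // nontrivial blossom slot in use
  std::vector<int> unusedblossoms;
  std::vector<double> dualvar;     // vertex duals (doubled)
  std::vector<double> blossomdual; // nontrivial blossom duals (doubled)
  std::vector<char> allowedge;     // per edge id: slack 0, usable
  std::deque<int> queue;           // S-vertices to scan

  static long long pack(int a, int b) {
    if (a > b) std::swap(a, b);
    return (long long)a * 0x100000000LL + b;
  }

  Matcher(const std::vector<int>& i_, const std::vector<int>& j_,
          const std::vector<double>& w_, int n_)
      : n(n_), m((int)i_.size()), ei(i_), ej(j_), ew(w_) {
    adj.assign(n, {});
    for (int k = 0; k < m; ++k) {
      adj[ei[k]].push_back(k);
      adj[ej[k]].push_back(k);
      eid[pack(ei[k], ej[k])] = k;
    }
    double maxweight = 0.0;
    for (int k = 0; k < m; ++k) maxweight = std::max(maxweight, ew[k]);
    mate.assign(n, -1);
    label.assign(2 * n, LBL_NONE);
    labeledge.assign(2 * n, {NOVERT, NOVERT});
    inblossom.resize(n);
    for (int v = 0; v < n; ++v) inblossom[v] = v;
    blossomparent.assign(2 * n, -1);
    blossombase.assign(2 * n, -1);
    for (int v = 0; v < n; ++v) blossombase[v] = v;
    blossomchilds.assign(2 * n, {});
    blossomedges.assign(2 * n, {});
    blossomused.assign(2 * n, 0);
    for (int b = 2 * n - 1; b >= n; --b) unusedblossoms.push_back(b);
    dualvar.assign(n, maxweight);
    blossomdual.assign(2 * n, 0.0);
    allowedge.assign(m, 0);
  }

  double slack(int k) const { return dualvar[ei[k]] + dualvar[ej[k]] - 2.0 * ew[k]; }
  double slackvw(int v, int w) const { return slack(eid.at(pack(v, w))); }

  void blossomLeaves(int b, std::vector<int>& out) const {
    if (b < n) {
      out.push_back(b);
    } else {
      for (int c : blossomchilds[b]) blossomLeaves(c, out);
    }
  }

  void assignLabel(int w, int t, int v) {
    int b = inblossom[w];
    if (dbg) Rcpp::Rcout << "assignLabel(" << w << "," << t << "," << v << ") b=" << b << "\n";
    label[w] = label[b] = t;
    if (v != NOVERT) {
      labeledge[w] = labeledge[b] = {v, w};
    } else {
      labeledge[w] = labeledge[b] = {NOVERT, NOVERT};
    }
    if (t == LBL_S) {
      std::vector<int> leaves;
      blossomLeaves(b, leaves);
      for (int u : leaves) queue.push_back(u);
    } else if (t == LBL_T) {
      int base = blossombase[b];
      assignLabel(mate[base], LBL_S, base);
    }
  }

  // Trace back from v and w to find the common ancestor (new blossom base),
  // or NOVERT if the paths end in different roots (an augmenting path).
  int scanBlossom(int v, int w) {
    std::vector<int> path;
    int base = NOVERT;
    while (v != NOVERT) {
      int b = inblossom[v];
      if (label[b] & LBL_CRUMB) {
        base = blossombase[b];
        break;
      }
      path.push_back(b);
      label[b] |= LBL_CRUMB;
      if (labeledge[b].first == NOVERT) {
        v = NOVERT;  // root of the tree (single vertex)
      } else {
        v = labeledge[b].first;
        b = inblossom[v];
        v = labeledge[b].first;  // step through the T-blossom
      }
      if (w != NOVERT) std::swap(v, w);
    }
    for (int b : path) label[b] &= ~LBL_CRUMB;
    return base;
  }

  void addBlossom(int base, int v, int w) {
    if (dbg) Rcpp::Rcout << "addBlossom(" << base << "," << v << "," << w << ") free=" << unusedblossoms.size() << "\n";
    int bb = inblossom[base];
    int bv = inblossom[v];
    int bw = inblossom[w];
    int b = unusedblossoms.back();
    unusedblossoms.pop_back();
    blossomused[b] = 1;
    blossombase[b] = base;
    blossomparent[b] = -1;
    blossomparent[bb] = b;
    std::vector<int> path;
    std::vector<std::pair<int, int>> edgs;
    edgs.push_back({v, w});
    while (bv != bb) {
      blossomparent[bv] = b;
      path.push_back(bv);
      edgs.push_back(labeledge[bv]);
      v = labeledge[bv].first;
      bv = inblossom[v];
    }
    path.push_back(bb);
    std::reverse(path.begin(), path.end());
    std::reverse(edgs.begin(), edgs.end());
    while (bw != bb) {
      blossomparent[bw] = b;
      path.push_back(bw);
      edgs.push_back({labeledge[bw].second, labeledge[bw].first});
      w = labeledge[bw].first;
      bw = inblossom[w];
    }
    blossomchilds[b] = std::move(path);
    blossomedges[b] = std::move(edgs);
    label[b] = LBL_S;
    labeledge[b] = labeledge[bb];
    blossomdual[b] = 0.0;
    std::vector<int> leaves;
    blossomLeaves(b, leaves);
    for (int u : leaves) {
      if (label[inblossom[u]] == LBL_T) queue.push_back(u);
      inblossom[u] = b;
    }
  }

  void allow(int v, int w) { allowedge[eid.at(pack(v, w))] = 1; }

  void expandBlossom(int b, bool endstage) {
    if (dbg) Rcpp::Rcout << "expandBlossom(" << b << "," << endstage << ")\n";
    for (int s : blossomchilds[b]) {
      blossomparent[s] = -1;
      if (s < n) {
        inblossom[s] = s;
      } else if (endstage && blossomdual[s] == 0.0) {
        expandBlossom(s, endstage);
      } else {
        std::vector<int> leaves;
        blossomLeaves(s, leaves);
        for (int u : leaves) inblossom[u] = s;
      }
    }
    if (!endstage && label[b] == LBL_T) {
      // The expanding blossom is on an alternating path; relabel the chain
      // of sub-blossoms between the entry point and the base.
      int entrychild = inblossom[labeledge[b].second];
      int nch = (int)blossomchilds[b].size();
      int j = 0;
      while (blossomchilds[b][j] != entrychild) ++j;
      int jstep;
      if (j & 1) {
        j -= nch;
        jstep = 1;
      } else {
        jstep = -1;
      }
      int v = labeledge[b].first, w = labeledge[b].second;
      auto at = [&](int idx) -> std::pair<int, int>& {
        return blossomedges[b][(idx % nch + nch) % nch];
      };
      auto childat = [&](int idx) -> int {
        return blossomchilds[b][(idx % nch + nch) % nch];
      };
      while (j != 0) {
        int p, q;
        if (jstep == 1) {
          p = at(j).first;
          q = at(j).second;
        } else {
          q = at(j - 1).first;
          p = at(j - 1).second;
        }
        label[w] = LBL_NONE;
        label[q] = LBL_NONE;
        assignLabel(w, LBL_T, v);
        allow(p, q);
        j += jstep;
        if (jstep == 1) {
          v = at(j).first;
          w = at(j).second;
        } else {
          w = at(j - 1).first;
          v = at(j - 1).second;
        }
        allow(v, w);
        j += jstep;
      }
      int bw = childat(j);
      label[w] = LBL_T;
      label[bw] = LBL_T;
      labeledge[w] = {v, w};
      labeledge[bw] = {v, w};
      j += jstep;
      while (childat(j) != entrychild) {
        int bv = childat(j);
        if (label[bv] == LBL_S) {
          j += jstep;
          continue;
        }
        int u = NOVERT;
        std::vector<int> leaves;
        blossomLeaves(bv, leaves);
        for (int lv : leaves) {
          if (label[lv] != LBL_NONE) {
            u = lv;
            break;
          }
        }
        if (u != NOVERT) {
          label[u] = LBL_NONE;
          label[mate[blossombase[bv]]] = LBL_NONE;
          assignLabel(u, LBL_T, labeledge[u].first);
        }
        j += jstep;
      }
    }
    label[b] = LBL_NONE;
    labeledge[b] = {NOVERT, NOVERT};
    blossomparent[b] = -1;
    blossombase[b] = -1;
    blossomdual[b] = 0.0;
    blossomchilds[b].clear();
    blossomedges[b].clear();
    blossomused[b] = 0;
    unusedblossoms.push_back(b);
  }

  // Swap matched/unmatched edges over the alternating path through blossom b
  // between vertex v and the blossom base.
  void augmentBlossom(int b, int v) {
    int t = v;
    while (blossomparent[t] != b) t = blossomparent[t];
    if (t >= n) augmentBlossom(t, v);
    int nch = (int)blossomchilds[b].size();
    int i = 0;
    while (blossomchilds[b][i] != t) ++i;
    int j = i, jstep;
    if (i & 1) {
      j -= nch;
      jstep = 1;
    } else {
      jstep = -1;
    }
    auto at = [&](int idx) -> std::pair<int, int>& {
      return blossomedges[b][(idx % nch + nch) % nch];
    };
    auto childat = [&](int idx) -> int {
      return blossomchilds[b][(idx % nch + nch) % nch];
    };
    while (j != 0) {
      j += jstep;
      t = childat(j);
      int w, x;
      if (jstep == 1) {
        w = at(j).first;
        x = at(j).second;
      } else {
        x = at(j - 1).first;
        w = at(j - 1).second;
      }
      if (t >= n) augmentBlossom(t, w);
      j += jstep;
      t = childat(j);
      if (t >= n) augmentBlossom(t, x);
      mate[w] = x;
      mate[x] = w;
    }
    std::rotate(blossomchilds[b].begin(), blossomchilds[b].begin() + i,
                blossomchilds[b].end());
    std::rotate(blossomedges[b].begin(), blossomedges[b].begin() + i,
                blossomedges[b].end());
    blossombase[b] = blossombase[blossomchilds[b][0]];
  }

  void augmentMatching(int v, int w) {
    int starts[2][2] = {{v, w}, {w, v}};
    for (auto& sj : starts) {
      int s = sj[0], j = sj[1];
      while (true) {
        int bs = inblossom[s];
        if (bs >= n) augmentBlossom(bs, s);
        mate[s] = j;
        if (labeledge[bs].first == NOVERT) break;
        int t = labeledge[bs].first;
        int bt = inblossom[t];
        s = labeledge[bt].first;
        j = labeledge[bt].second;
        if (bt >= n) augmentBlossom(bt, j);
        mate[j] = s;
      }
    }
  }

  void run() {
    if (m == 0) return;
    long long guard = 0;
    while (true) {
      if (++guard > (long long)n + 2) Rcpp::stop("matching solver failed to terminate");
      if (dbg) Rcpp::Rcout << "=== stage " << guard << "\n";
      std::fill(label.begin(), label.end(), LBL_NONE);
      std::fill(labeledge.begin(), labeledge.end(),
                std::make_pair(NOVERT, NOVERT));
      std::fill(allowedge.begin(), allowedge.end(), 0);
      queue.clear();
      for (int v = 0; v < n; ++v) {
        if (mate[v] == -1 && label[inblossom[v]] == LBL_NONE)
          assignLabel(v, LBL_S, NOVERT);
      }
      bool augmented = false;
      while (true) {
        while (!queue.empty() && !augmented) {
          int v2 = queue.back();
          queue.pop_back();
          for (int k : adj[v2]) {
            int w2 = (ei[k] == v2) ? ej[k] : ei[k];
            int bv = inblossom[v2], bw = inblossom[w2];
            if (bv == bw) continue;
            if (!allowedge[k]) {
              if (slack(k) <= 0) allowedge[k] = 1;
            }
            if (allowedge[k]) {
              if (label[bw] == LBL_NONE) {
                assignLabel(w2, LBL_T, v2);
              } else if (label[bw] == LBL_S) {
                int base = scanBlossom(v2, w2);
                if (base != NOVERT) {
                  addBlossom(base, v2, w2);
                } else {
                  augmentMatching(v2, w2);
                  augmented = true;
                  break;
                }
              } else if (label[w2] == LBL_NONE) {
                label[w2] = LBL_T;
                labeledge[w2] = {v2, w2};
              }
            }
          }
        }
        if (augmented) break;

        // Dual adjustment: find the binding constraint.
        int deltatype = 1;
        double delta = dualvar[0];
        for (int v2 = 1; v2 < n; ++v2) delta = std::min(delta, dualvar[v2]);
        int deltaedge = -1, deltablossom = -1;
        for (int k = 0; k < m; ++k) {
          int bi = inblossom[ei[k]], bj = inblossom[ej[k]];
          if (bi == bj) continue;
          int li = label[bi] & 3, lj = label[bj] & 3;
          if (li == LBL_S && lj == LBL_S) {
            double d = slack(k) / 2.0;
            if (d < delta) {
              delta = d;
              deltatype = 3;
              deltaedge = k;
            }
          } else if ((li == LBL_S && lj == LBL_NONE) ||
                     (lj == LBL_S && li == LBL_NONE)) {
            double d = slack(k);
            if (d < delta) {
              delta = d;
              deltatype = 2;
              deltaedge = k;
            }
          }
        }
        for (int b = n; b < 2 * n; ++b) {
          if (blossomused[b] && blossomparent[b] == -1 && label[b] == LBL_T) {
            if (blossomdual[b] < delta) {
              delta = blossomdual[b];
              deltatype = 4;
              deltablossom = b;
            }
          }
        }

        for (int v2 = 0; v2 < n; ++v2) {
          int lb = label[inblossom[v2]] & 3;
          if (lb == LBL_S)
            dualvar[v2] -= delta;
          else if (lb == LBL_T)
            dualvar[v2] += delta;
        }
        for (int b = n; b < 2 * n; ++b) {
          if (blossomused[b] && blossomparent[b] == -1) {
            if (label[b] == LBL_S)
              blossomdual[b] += delta;
            else if (label[b] == LBL_T)
              blossomdual[b] -= delta;
          }
        }

        if (dbg) Rcpp::Rcout << "delta type=" << deltatype << " val=" << delta << "\n";
        if (deltatype == 1) {
          break;  // optimum reached
        } else if (deltatype == 2) {
          allowedge[deltaedge] = 1;
          int vq = (label[inblossom[ei[deltaedge]]] & 3) == LBL_S
                       ? ei[deltaedge]
                       : ej[deltaedge];
          queue.push_back(vq);
        } else if (deltatype == 3) {
          allowedge[deltaedge] = 1;
          queue.push_back(ei[deltaedge]);
        } else {
          expandBlossom(deltablossom, false);
        }
      }
      if (!augmented) break;
      for (int b = n; b < 2 * n; ++b) {
        if (blossomused[b] && blossomparent[b] == -1 && label[b] == LBL_S &&
            blossomdual[b] == 0.0) {
          expandBlossom(b, true);
        }
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".mwm_cpp")]]
Rcpp::IntegerVector mwm_cpp(Rcpp::IntegerVector i, Rcpp::IntegerVector j,
                            Rcpp::NumericVector w, int n) {
  int m = i.size();
  std::vector<int> vi(m), vj(m);
  std::vector<double> vw(m);
  for (int k = 0; k < m; ++k) {
    vi[k] = i[k] - 1;
    vj[k] = j[k] - 1;
    vw[k] = w[k];
    if (vi[k] < 0 || vi[k] >= n || vj[k] < 0 || vj[k] >= n || vi[k] == vj[k])
      Rcpp::stop("invalid edge endpoint");
  }
  Matcher M(vi, vj, vw, n);
  M.dbg = (std::getenv("LINCHROM_MWM_DEBUG") != nullptr);
  M.run();
  Rcpp::IntegerVector mate(n);
  for (int v = 0; v < n; ++v) mate[v] = (M.mate[v] == -1) ? NA_INTEGER : M.mate[v] + 1;
  return mate;
}
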