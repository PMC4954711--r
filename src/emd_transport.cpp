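#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Exact solver for the balanced transportation problem behind the Earth
// Mover's Distance: minimize sum c_ij f_ij subject to row sums = supply,
// column sums = demand, f >= 0, with sum(supply) == sum(demand).
//
// Classic transportation simplex: northwest-corner initial basis (kept at
// m + n - 1 cells through degeneracy), MODI potentials computed by BFS on
// the basis tree, entering variable by most-negative reduced cost
// (switching to Bland's rule if pivoting stalls), leaving variable the
// minimum-flow '-' cell on the unique basis cycle.

struct Cell { int i, j; };

// [[Rcpp::export]]
List transport_simplex_cpp(NumericVector supply, NumericVector demand,
                           NumericMatrix cost, double tol = 1e-10) {
  const int m = supply.size(), n = demand.size();
  if (cost.nrow() != m || cost.ncol() != n)
    stop("cost matrix dimensions do not match supply/demand");
  double ssum = 0.0, dsum = 0.0;
  for (int i = 0; i < m; ++i) ssum += supply[i];
  for (int j = 0; j < n; ++j) dsum += demand[j];
  if (std::fabs(ssum - dsum) > 1e-8 * std::max(1.0, ssum))
    stop("transportation problem must be balanced");

  NumericMatrix X(m, n);
  std::vector<char> basis(m * n, 0);
  std::vector< std::vector<int> > row_adj(m), col_adj(n);

  // northwest-corner start, always m + n - 1 basic cells
  {
    std::vector<double> a(supply.begin(), supply.end());
    std::vector<double> b(demand.begin(), demand.end());
    int i = 0, j = 0;
    while (i < m && j < n) {
      double f = std::min(a[i], b[j]);
      X(i, j) = f;
      basis[i * n + j] = 1;
      row_adj[i].push_back(j);
      col_adj[j].push_back(i);
      a[i] -= f; b[j] -= f;
      if (i == m - 1 && j == n - 1) break;
      // advance one index only; on ties this leaves a zero-flow basic cell
      if (a[i] <= b[j] && i < m - 1) ++i;
      else if (j < n - 1) ++j;
      else ++i;
    }
  }

  std::vector<double> u(m), v(n);
  std::vector<char> udone(m), vdone(n);
  const long maxit = 2000L + 50L * (long)(m + n) * (m + n);
  long it = 0;
  bool bland = false;

  for (;; ++it) {
    if (it > maxit) stop("transportation simplex failed to converge");
    if (it == maxit / 2) bland = true;  // anti-cycling fallback

    // potentials via BFS over the basis tree
    std::fill(udone.begin(), udone.end(), 0);
    std::fill(vdone.begin(), vdone.end(), 0);
    u[0] = 0.0; udone[0] = 1;
    std::queue<int> q;  // nodes: rows 0..m-1, cols m..m+n-1
    q.push(0);
    while (!q.empty()) {
      int node = q.front(); q.pop();
      if (node < m) {
        for (size_t k = 0; k < row_adj[node].size(); ++k) {
          int j = row_adj[node][k];
          if (!vdone[j]) { v[j] = cost(node, j) - u[node]; vdone[j] = 1; q.push(m + j); }
        }
      } else {
        int j = node - m;
        for (size_t k = 0; k < col_adj[j].size(); ++k) {
          int i = col_adj[j][k];
          if (!udone[i]) { u[i] = cost(i, j) - v[j]; udone[i] = 1; q.push(i); }
        }
      }
    }

    // entering cell
    int ei = -1, ej = -1;
    double best = -tol;
    for (int i = 0; i < m && (ei < 0 || !bland); ++i) {
      for (int j = 0; j < n; ++j) {
        if (basis[i * n + j]) continue;
        double rc = cost(i, j) - u[i] - v[j];
        if (rc < best) {
          best = rc; ei = i; ej = j;
          if (bland) break;  // first negative in row-major order
        }
      }
    }
    if (ei < 0) break;  // optimal

    // unique path row ei -> col ej through the basis tree
    std::vector<int> par(m + n, -1);
    std::vector<char> seen(m + n, 0);
    std::queue<int> bq;
    bq.push(ei); seen[ei] = 1;
    while (!bq.empty()) {
      int node = bq.front(); bq.pop();
      if (node == m + ej) break;
      if (node < m) {
        for (size_t k = 0; k < row_adj[node].size(); ++k) {
          int nj = m + row_adj[node][k];
          if (!seen[nj]) { seen[nj] = 1; par[nj] = node; bq.push(nj); }
        }
      } else {
        int j = node - m;
        for (size_t k = 0; k < col_adj[j].size(); ++k) {
          int ni = col_adj[j][k];
          if (!seen[ni]) { seen[ni] = 1; par[ni] = node; bq.push(ni); }
        }
      }
    }
    if (!seen[m + ej]) stop("basis tree disconnected");  // cannot happen

    std::vector<Cell> path;  // cells from row ei to col ej
    {
      std::vector<int> nodes;
      for (int node = m + ej; node != -1; node = par[node]) nodes.push_back(node);
      // nodes: col ej ... row ei (reversed); consecutive pairs are cells
      for (size_t k = 0; k + 1 < nodes.size(); ++k) {
        int a = nodes[k + 1], b = nodes[k];  // edge a->b along path from ei
        Cell c;
        if (a < m) { c.i = a; c.j = b - m; } else { c.i = b; c.j = a - m; }
        path.push_back(c);
      }
      std::reverse(path.begin(), path.end());  // now row ei -> col ej order
    }

    // signs along path: -, +, -, ... ; theta from '-' cells
    double theta = R_PosInf;
    int leave = -1;
    for (size_t k = 0; k < path.size(); k += 2) {
      double f = X(path[k].i, path[k].j);
      if (f < theta - 1e-15) { theta = f; leave = (int)k; }
    }
    X(ei, ej) += theta;
    for (size_t k = 0; k < path.size(); ++k) {
      if (k % 2 == 0) X(path[k].i, path[k].j) -= theta;
      else            X(path[k].i, path[k].j) += theta;
    }

    // pivot: entering joins basis, leaving cell departs
    basis[ei * n + ej] = 1;
    row_adj[ei].push_back(ej);
    col_adj[ej].push_back(ei);
    const int li = path[leave].i, lj = path[leave].j;
    basis[li * n + lj] = 0;
    X(li, lj) = 0.0;
    for (size_t k = 0; k < row_adj[li].size(); ++k)
      if (row_adj[li][k] == lj) { row_adj[li].erase(row_adj[li].begin() + k); break; }
    for (size_t k = 0; k < col_adj[lj].size(); ++k)
      if (col_adj[lj][k] == li) { col_adj[lj].erase(col_adj[lj].begin() + k); break; }
  }

  double work = 0.0, total = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) { work += cost(i, j) * X(i, j); total += X(i, j); }

  return List::create(_["flow"] = X, _["work"] = work,
                      _["total_flow"] = total, _["iterations"] = (double)it);
}
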