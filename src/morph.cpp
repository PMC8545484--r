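#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Grayscale morphology with a spherical (non-flat) structuring element of
// radius r pixels: height h(dx,dy) = sqrt(r^2 - dx^2 - dy^2) over the disc.
// Erosion followed by dilation with this element is the classical
// rolling-ball background estimate (the ball rolled under the surface).

static void ball_offsets(double radius,
                         std::vector<int> &dx, std::vector<int> &dy,
                         std::vector<double> &h) {
  int r = (int)std::floor(radius);
  for (int i = -r; i <= r; ++i) {
    for (int j = -r; j <= r; ++j) {
      double d2 = (double)i * i + (double)j * j;
      if (d2 <= radius * radius) {
        dx.push_back(j);
        dy.push_back(i);
        h.push_back(std::sqrt(radius * radius - d2));
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_rolling_ball_background")]]
NumericMatrix cpp_rolling_ball_background(NumericMatrix img, double radius) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> dx, dy;
  std::vector<double> h;
  ball_offsets(radius, dx, dy, h);
  size_t m = dx.size();
  NumericMatrix ero(nr, nc), bg(nr, nc);
  // erosion: min over offsets of img(y+dy, x+dx) - h; out-of-bounds treated
  // as absent (edge pixels use the in-bounds part of the ball)
  for (int x = 0; x < nc; ++x) {
    for (int y = 0; y < nr; ++y) {
      double v = std::numeric_limits<double>::infinity();
      for (size_t k = 0; k < m; ++k) {
        int yy = y + dy[k], xx = x + dx[k];
        if (yy < 0 || yy >= nr || xx < 0 || xx >= nc) continue;
        double cand = img(yy, xx) - h[k];
        if (cand < v) v = cand;
      }
      ero(y, x) = v;
    }
  }
  // dilation of the eroded surface
  for (int x = 0; x < nc; ++x) {
    for (int y = 0; y < nr; ++y) {
      double v = -std::numeric_limits<double>::infinity();
      for (size_t k = 0; k < m; ++k) {
        int yy = y - dy[k], xx = x - dx[k];
        if (yy < 0 || yy >= nr || xx < 0 || xx >= nc) continue;
        double cand = ero(yy, xx) + h[k];
        if (cand > v) v = cand;
      }
      bg(y, x) = v;
    }
  }
  return bg;
}

// Two-pass connected-component labeling with union-find.
// connectivity: 4 or 8.

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0); // parent[i] for label i; labels start at 1
  int next = 1;

  auto find = [&](int a) {
    while (parent[a] != a) {
      parent[a] = parent[parent[a]];
      a = parent[a];
    }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  for (int x = 0; x < nc; ++x) {
    for (int y = 0; y < nr; ++y) {
      if (!mask(y, x)) continue;
      // previously-visited neighbours in column-major scan order
      int neigh[4];
      int nn = 0;
      if (y > 0 && mask(y - 1, x)) neigh[nn++] = lab(y - 1, x);
      if (x > 0 && mask(y, x - 1)) neigh[nn++] = lab(y, x - 1);
      if (connectivity == 8) {
        if (x > 0 && y > 0 && mask(y - 1, x - 1)) neigh[nn++] = lab(y - 1, x - 1);
        if (x > 0 && y < nr - 1 && mask(y + 1, x - 1)) neigh[nn++] = lab(y + 1, x - 1);
      }
      if (nn == 0) {
        parent.push_back(next);
        lab(y, x) = next++;
      } else {
        int mn = neigh[0];
        for (int k = 1; k < nn; ++k) if (neigh[k] < mn) mn = neigh[k];
        lab(y, x) = mn;
        for (int k = 0; k < nn; ++k) unite(mn, neigh[k]);
      }
    }
  }
  // flatten and relabel consecutively
  std::vector<int> newlab(next, 0);
  int count = 0;
  for (int i = 1; i < next; ++i) {
    int r = find(i);
    if (newlab[r] == 0) newlab[r] = ++count;
  }
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y)
      if (lab(y, x) > 0) lab(y, x) = newlab[find(lab(y, x))];
  return lab;
}
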