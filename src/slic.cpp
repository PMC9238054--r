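#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// SLIC superpixel segmentation of a single-channel image.
//
// Grid-initialized local k-means in (intensity, row, col) space with the
// distance D^2 = (dI / compactness)^2 + (dr^2 + dc^2) / S^2, where S is the
// sampling interval sqrt(N / k). Centers are perturbed to the lowest-gradient
// position in their 3x3 neighborhood before iterating. A final connectivity
// pass relabels 4-connected components and merges fragments smaller than
// S^2/4 (or fragments of a label that has a larger component elsewhere) into
// the nearest previously-seen adjacent superpixel. Labels are 1..K.
//
// [[Rcpp::export(name = ".slic_cpp")]]
IntegerMatrix slic_cpp(NumericMatrix img, int n_target, double compactness,
                       int max_iter = 10) {
  const int nr = img.nrow(), nc = img.ncol();
  const double N = (double)nr * nc;
  const double S = std::sqrt(N / n_target);

  // --- grid initialization ---
  int ny = std::max(1, (int)std::lround(nr / S));
  int nx = std::max(1, (int)std::lround(nc / S));
  int k = ny * nx;
  std::vector<double> cr(k), cc(k), ci(k);
  {
    int idx = 0;
    for (int gy = 0; gy < ny; ++gy) {
      for (int gx = 0; gx < nx; ++gx, ++idx) {
        double r = (gy + 0.5) * nr / ny - 0.5;
        double c = (gx + 0.5) * nc / nx - 0.5;
        // perturb to lowest gradient in 3x3
        int r0 = std::min(std::max((int)std::lround(r), 1), nr - 2);
        int c0 = std::min(std::max((int)std::lround(c), 1), nc - 2);
        double best = R_PosInf;
        int br = r0, bc = c0;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            int rr = r0 + dr, cc2 = c0 + dc;
            if (rr < 1 || rr > nr - 2 || cc2 < 1 || cc2 > nc - 2) continue;
            double gx2 = img(rr, cc2 + 1) - img(rr, cc2 - 1);
            double gy2 = img(rr + 1, cc2) - img(rr - 1, cc2);
            double g = gx2 * gx2 + gy2 * gy2;
            if (g < best) { best = g; br = rr; bc = cc2; }
          }
        }
        cr[idx] = br; cc[idx] = bc; ci[idx] = img(br, bc);
      }
    }
  }

  std::vector<int> label(nr * nc, -1);
  std::vector<double> dist(nr * nc);
  const double inv_m2 = 1.0 / (compactness * compactness);
  const double inv_S2 = 1.0 / (S * S);
  const int win = (int)std::ceil(1.5 * S);

  for (int iter = 0; iter < max_iter; ++iter) {
    // reset distances (keep current assignment valid as fallback)
    for (int p = 0; p < nr * nc; ++p) {
      if (label[p] >= 0) {
        int r = p % nr, c = p / nr;
        double dI = img(r, c) - ci[label[p]];
        double dr = r - cr[label[p]], dc = c - cc[label[p]];
        dist[p] = dI * dI * inv_m2 + (dr * dr + dc * dc) * inv_S2;
      } else {
        dist[p] = R_PosInf;
      }
    }
    for (int j = 0; j < k; ++j) {
      int rlo = std::max(0, (int)cr[j] - win), rhi = std::min(nr - 1, (int)cr[j] + win);
      int clo = std::max(0, (int)cc[j] - win), chi = std::min(nc - 1, (int)cc[j] + win);
      for (int c = clo; c <= chi; ++c) {
        for (int r = rlo; r <= rhi; ++r) {
          double dI = img(r, c) - ci[j];
          double dr = r - cr[j], dc = c - cc[j];
          double d = dI * dI * inv_m2 + (dr * dr + dc * dc) * inv_S2;
          int p = c * nr + r;
          if (d < dist[p]) { dist[p] = d; label[p] = j; }
        }
      }
    }
    // update centers
    std::vector<double> sr(k, 0), sc(k, 0), si(k, 0);
    std::vector<int> cnt(k, 0);
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        int j = label[c * nr + r];
        if (j < 0) continue;
        sr[j] += r; sc[j] += c; si[j] += img(r, c); cnt[j]++;
      }
    }
    for (int j = 0; j < k; ++j) {
      if (cnt[j] > 0) {
        cr[j] = sr[j] / cnt[j];
        cc[j] = sc[j] / cnt[j];
        ci[j] = si[j] / cnt[j];
      }
    }
  }

  // --- connectivity enforcement ---
  const int min_size = std::max(1, (int)(S * S / 4.0));
  std::vector<int> newlab(nr * nc, -1);
  int next = 0;
  std::vector<int> comp;
  comp.reserve(1024);
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int p = c * nr + r;
      if (newlab[p] >= 0) continue;
      // adjacent already-labeled component (for possible merging)
      int adj = -1;
      if (r > 0 && newlab[p - 1] >= 0) adj = newlab[p - 1];
      else if (c > 0 && newlab[p - nr] >= 0) adj = newlab[p - nr];
      // flood fill this component
      comp.clear();
      std::queue<int> q;
      q.push(p);
      newlab[p] = next;
      comp.push_back(p);
      while (!q.empty()) {
        int cur = q.front(); q.pop();
        int rr = cur % nr, cc2 = cur / nr;
        for (int d = 0; d < 4; ++d) {
          int r2 = rr + dr4[d], c2 = cc2 + dc4[d];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          int p2 = c2 * nr + r2;
          if (newlab[p2] < 0 && label[p2] == label[p]) {
            newlab[p2] = next;
            comp.push_back(p2);
            q.push(p2);
          }
        }
      }
      if ((int)comp.size() < min_size && adj >= 0) {
        for (int p2 : comp) newlab[p2] = adj;
      } else {
        ++next;
      }
    }
  }

  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = newlab[c * nr + r] + 1;
  return out;
}
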