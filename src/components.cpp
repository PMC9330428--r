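// 26-connected component labeling for 3D integer masks.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const long V = (long)Z * Y * X;
  IntegerVector lab(V, 0);
  lab.attr("dim") = dims;
  auto vid = [&](int z, int y, int x) { return (long)z + (long)Z * (y + (long)Y * x); };
  int next = 0;
  std::vector<long> stack;
  for (long s = 0; s < V; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      long v = stack.back(); stack.pop_back();
      int z = (int)(v % Z);
      int rem = (int)(v / Z);
      int y = rem % Y, x = rem / Y;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx; if (xx < 0 || xx >= X) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= Y) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            int zz = z + dz; if (zz < 0 || zz >= Z) continue;
            long u = vid(zz, yy, xx);
            if (mask[u] != 0 && lab[u] == 0) { lab[u] = next; stack.push_back(u); }
          }
        }
      }
    }
  }
  return lab;
}
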