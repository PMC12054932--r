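#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Monte Carlo replicates of one virtual-study-area scenario.
//
// Each replicate scatters n_targets targets and n_markers markers uniformly
// at random on the unit square, then collects the raw counts both estimators
// need:
//   - linear window: a strip of strip_rows FOV-rows along the bottom edge,
//     swept left to right until x_stop targets are enclosed; the window
//     length is the x-coordinate of the x_stop-th target and the marker
//     count is the number of markers in the strip at or left of it.
//   - FOVS: the square is divided into grid_side^2 half-open cells (so each
//     specimen belongs to exactly one cell); n3c calibration and n3e
//     extrapolation cells are drawn without replacement, disjointly.
//
// Returns one row per replicate:
//   [0] markers in linear window (NA if the strip held < x_stop targets)
//   [1] window length (x-coordinate of the stopping target)
//   [2] calibration mean per FOV
//   [3] calibration sample SD (Bessel)
//   [4] total specimens counted during calibration
//   [5] rare (marker) specimens in the extrapolation cells
//
// Uses R's RNG stream, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix cpp_sim_replicates(int n_rep, int n_targets, int n_markers,
                                 int grid_side, int strip_rows, int x_stop,
                                 int n3c, int n3e) {
  if (n_rep < 1 || n_targets < 1 || n_markers < 1 || grid_side < 1 ||
      strip_rows < 1 || strip_rows > grid_side || x_stop < 1 ||
      n3c < 2 || n3e < 1)
    stop("invalid simulation parameters");
  const int n_cells = grid_side * grid_side;
  if (n3c + n3e > n_cells)
    stop("n3c + n3e exceeds the number of grid cells");

  NumericMatrix out(n_rep, 6);
  std::vector<int> tab_t(n_cells), tab_m(n_cells), cells(n_cells);
  std::vector<double> strip_tx, strip_mx;
  strip_tx.reserve(2 * (n_targets * strip_rows / grid_side + 64));
  strip_mx.reserve(2 * (n_markers * strip_rows / grid_side + 64));
  const double strip_h = (double)strip_rows / grid_side;

  for (int r = 0; r < n_rep; ++r) {
    std::fill(tab_t.begin(), tab_t.end(), 0);
    std::fill(tab_m.begin(), tab_m.end(), 0);
    strip_tx.clear();
    strip_mx.clear();

    for (int i = 0; i < n_targets; ++i) {
      double u = unif_rand(), v = unif_rand();
      int cx = (int)(u * grid_side), cy = (int)(v * grid_side);
      if (cx >= grid_side) cx = grid_side - 1;  // guard u == 1 edge case
      if (cy >= grid_side) cy = grid_side - 1;
      ++tab_t[cy * grid_side + cx];
      if (v < strip_h) strip_tx.push_back(u);
    }
    for (int i = 0; i < n_markers; ++i) {
      double u = unif_rand(), v = unif_rand();
      int cx = (int)(u * grid_side), cy = (int)(v * grid_side);
      if (cx >= grid_side) cx = grid_side - 1;
      if (cy >= grid_side) cy = grid_side - 1;
      ++tab_m[cy * grid_side + cx];
      if (v < strip_h) strip_mx.push_back(u);
    }

    // linear window
    if ((int)strip_tx.size() >= x_stop) {
      std::nth_element(strip_tx.begin(), strip_tx.begin() + (x_stop - 1),
                       strip_tx.end());
      double cut = strip_tx[x_stop - 1];
      int nwin = 0;
      for (double mx : strip_mx)
        if (mx <= cut) ++nwin;
      out(r, 0) = nwin;
      out(r, 1) = cut;
    } else {
      out(r, 0) = NA_REAL;
      out(r, 1) = NA_REAL;
    }

    // FOVS cells: partial Fisher-Yates draw of n3c + n3e distinct cells
    for (int i = 0; i < n_cells; ++i) cells[i] = i;
    const int k = n3c + n3e;
    for (int i = 0; i < k; ++i) {
      int j = i + (int)(unif_rand() * (n_cells - i));
      if (j >= n_cells) j = n_cells - 1;
      std::swap(cells[i], cells[j]);
    }
    double sum = 0.0, sumsq = 0.0;
    for (int i = 0; i < n3c; ++i) {
      double c = tab_t[cells[i]];
      sum += c;
      sumsq += c * c;
    }
    double mean = sum / n3c;
    double var = (sumsq - n3c * mean * mean) / (n3c - 1);
    if (var < 0) var = 0;
    int rare = 0;
    for (int i = n3c; i < k; ++i) rare += tab_m[cells[i]];
    out(r, 2) = mean;
    out(r, 3) = std::sqrt(var);
    out(r, 4) = sum;
    out(r, 5) = rare;

    if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
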