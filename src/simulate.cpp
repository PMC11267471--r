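#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Reflect a coordinate into [0, w] (reflecting habitat boundary).
static double reflect(double v, double w) {
  if (w <= 0) return 0.0;
  for (int it = 0; it < 64; ++it) {
    if (v < 0) v = -v;
    else if (v > w) v = 2.0 * w - v;
    else return v;
  }
  // pathological sigma >> arena: clamp
  if (v < 0) v = 0;
  if (v > w) v = w;
  return v;
}

// One gamete (0/1 alt-allele copy) from a diploid dosage.
static inline int gamete(int dosage) {
  if (dosage == 0) return 0;
  if (dosage == 2) return 1;
  return (unif_rand() < 0.5) ? 0 : 1;
}

// Forward-time continuous-space simulator with constant N, uniform mother
// choice, Gaussian mate-choice kernel (axial SD mating_radius), selfing,
// clonal reproduction with Gaussian clone displacement, Mendelian
// segregation at unlinked biallelic loci, and reflecting boundaries.
// Offspring position = mother + N(0, sigma_g^2) per axis.  Uses the R RNG.
// [[Rcpp::export(name = ".sim_forward_cpp")]]
List sim_forward_cpp(IntegerMatrix geno0, NumericVector x0, NumericVector y0,
                     double W, double H, int G, double sigma_g,
                     double mating_radius, double selfing_rate,
                     double clonal_rate, double clonal_sd) {
  const int N = geno0.nrow();
  const int L = geno0.ncol();
  std::vector<int> geno(geno0.begin(), geno0.end());       // column-major N x L
  std::vector<int> gnew(geno.size());
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  std::vector<double> xn(N), yn(N);
  std::vector<int> genet(N), genet_new(N);
  for (int i = 0; i < N; ++i) genet[i] = i + 1;
  int next_genet = N + 1;

  std::vector<int> mother(N), father(N);
  std::vector<int> isclone(N);
  std::vector<double> mx(N), my(N), fx(N), fy(N);

  // spatial grid for mate lookup
  const double cut = 4.0 * mating_radius;
  double cell = (mating_radius > 0) ? mating_radius : 1.0;
  int nx = std::max(1, (int)std::floor(W / cell));
  int ny = std::max(1, (int)std::floor(H / cell));
  if (nx * ny > 4 * N) {                       // keep occupancy sensible
    double target = std::sqrt((double)(nx * ny) / (4.0 * N));
    nx = std::max(1, (int)(nx / target));
    ny = std::max(1, (int)(ny / target));
  }
  std::vector<int> head(nx * ny), nxt(N);
  std::vector<int> cand;
  std::vector<double> cw;

  const double inv2m2 = (mating_radius > 0)
    ? 1.0 / (2.0 * mating_radius * mating_radius) : 0.0;

  for (int gen = 0; gen < G; ++gen) {
    // index adults on the grid
    std::fill(head.begin(), head.end(), -1);
    double cw_x = W / nx, cw_y = H / ny;
    for (int i = 0; i < N; ++i) {
      int cx = std::min(nx - 1, std::max(0, (int)(x[i] / cw_x)));
      int cy = std::min(ny - 1, std::max(0, (int)(y[i] / cw_y)));
      int c = cy * nx + cx;
      nxt[i] = head[c];
      head[c] = i;
    }
    int rx = (mating_radius > 0) ? (int)std::ceil(cut / cw_x) : nx;
    int ry = (mating_radius > 0) ? (int)std::ceil(cut / cw_y) : ny;

    for (int k = 0; k < N; ++k) {
      int m = (int)(unif_rand() * N);
      if (m >= N) m = N - 1;
      mother[k] = m;
      mx[k] = x[m]; my[k] = y[m];
      if (unif_rand() < clonal_rate) {
        // asexual: copy genotype and genet, displace position
        isclone[k] = 1;
        father[k] = -1;
        fx[k] = NA_REAL; fy[k] = NA_REAL;
        for (int l = 0; l < L; ++l) gnew[k + (size_t)l * N] = geno[m + (size_t)l * N];
        genet_new[k] = genet[m];
        xn[k] = reflect(x[m] + norm_rand() * clonal_sd, W);
        yn[k] = reflect(y[m] + norm_rand() * clonal_sd, H);
        continue;
      }
      isclone[k] = 0;
      int f;
      if (unif_rand() < selfing_rate || mating_radius <= 0) {
        f = m;
      } else {
        // kernel-weighted father among adults within 4 * mating_radius
        cand.clear(); cw.clear();
        double tot = 0.0;
        int cx = std::min(nx - 1, std::max(0, (int)(x[m] / cw_x)));
        int cy = std::min(ny - 1, std::max(0, (int)(y[m] / cw_y)));
        for (int dy = -ry; dy <= ry; ++dy) {
          int gy = cy + dy;
          if (gy < 0 || gy >= ny) continue;
          for (int dx = -rx; dx <= rx; ++dx) {
            int gx = cx + dx;
            if (gx < 0 || gx >= nx) continue;
            for (int i = head[gy * nx + gx]; i != -1; i = nxt[i]) {
              if (i == m) continue;
              double ddx = x[i] - x[m], ddy = y[i] - y[m];
              double r2 = ddx * ddx + ddy * ddy;
              if (mating_radius > 0 && r2 > cut * cut) continue;
              double w = std::exp(-r2 * inv2m2);
              cand.push_back(i);
              cw.push_back(w);
              tot += w;
            }
          }
        }
        if (cand.empty() || tot <= 0.0) {
          f = m;                                   // isolated: fall back to selfing
        } else {
          double u = unif_rand() * tot, acc = 0.0;
          f = cand.back();
          for (size_t c = 0; c < cand.size(); ++c) {
            acc += cw[c];
            if (u <= acc) { f = cand[c]; break; }
          }
        }
      }
      father[k] = f;
      fx[k] = x[f]; fy[k] = y[f];
      for (int l = 0; l < L; ++l) {
        size_t off = (size_t)l * N;
        gnew[k + off] = gamete(geno[m + off]) + gamete(geno[f + off]);
      }
      genet_new[k] = next_genet++;
      xn[k] = reflect(x[m] + norm_rand() * sigma_g, W);
      yn[k] = reflect(y[m] + norm_rand() * sigma_g, H);
    }
    geno.swap(gnew);
    x.swap(xn); y.swap(yn);
    genet.swap(genet_new);
  }

  IntegerMatrix gout(N, L);
  std::copy(geno.begin(), geno.end(), gout.begin());
  return List::create(
    _["genotypes"] = gout,
    _["x"] = NumericVector(x.begin(), x.end()),
    _["y"] = NumericVector(y.begin(), y.end()),
    _["genet"] = IntegerVector(genet.begin(), genet.end()),
    _["mother"] = IntegerVector(mother.begin(), mother.end()),
    _["father"] = IntegerVector(father.begin(), father.end()),
    _["is_clone"] = IntegerVector(isclone.begin(), isclone.end()),
    _["mother_x"] = NumericVector(mx.begin(), mx.end()),
    _["mother_y"] = NumericVector(my.begin(), my.end()),
    _["father_x"] = NumericVector(fx.begin(), fx.end()),
    _["father_y"] = NumericVector(fy.begin(), fy.end()));
}
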