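# Shared fixtures, memoized so expensive constructions (landmarks,
# flattening) run once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

sphere_head <- function(refinement = 3) {
  cached(paste0("sphere_head_", refinement),
         synthetic_head(56, c(1, 1, 1), refinement = refinement))
}

sphere_landmarks <- function(refinement = 3) {
  cached(paste0("sphere_landmarks_", refinement),
         compute_10_5_landmarks(sphere_head(refinement)))
}

# effective sphere radius of the discretized fixture (from measured HC)
sphere_radius <- function(refinement = 3) {
  head_circumference(sphere_head(refinement)) / (2 * pi)
}

default_head <- function(refinement = 2) {
  cached(paste0("default_head_", refinement),
         synthetic_head(56, refinement = refinement))
}

default_landmarks <- function(refinement = 2) {
  cached(paste0("default_landmarks_", refinement),
         compute_10_5_landmarks(default_head(refinement)))
}

# developable cylinder strip: radius r, 100 degrees, height h
cylinder_panel <- function(r = 80, h = 60, na = 41, nh = 25) {
  phi <- seq(-50, 50, length.out = na) * pi / 180
  hh <- seq(0, h, length.out = nh)
  g <- expand.grid(a = phi, z = hh)
  V <- cbind(r * sin(g$a), g$z, r * cos(g$a))
  idx <- function(i, j) (j - 1) * na + i
  F <- matrix(NA_integer_, 0, 3)
  for (j in seq_len(nh - 1)) for (i in seq_len(na - 1)) {
    F <- rbind(F, c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
               c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  panel_surface(trimesh(V, F), seq_len(nrow(V)), integer(0),
                data.frame(from = integer(), to = integer(), loop = character()),
                "left")
}

# 16-optode probe: 3 anchored dummies + a bilateral patch of rigid
# 30 mm source-detector pairs, flexibly tied to the anchors
probe_16 <- function() {
  ang <- seq(0, 2 * pi, length.out = 14)[-14]
  patch <- cbind(c(-45 + 12 * cos(ang[1:6]), 45 + 12 * cos(ang[7:13])),
                 c(20 + 12 * sin(ang[1:6]), 20 + 12 * sin(ang[7:13])))
  op <- data.frame(
    x = c(0, 0, 0, patch[, 1]),
    y = c(70, 0, -70, patch[, 2]),
    z = c(55, 98, 55, rep(80, 13)),
    kind = c(rep("dummy", 3), rep(c("source", "detector"), length.out = 13)),
    grommet = "#default", rotation = 0)
  sp <- rbind(
    data.frame(i = 4:8, j = 5:9, rest = 30),
    data.frame(i = 10:15, j = 11:16, rest = 30),
    data.frame(i = c(2, 2), j = c(6, 12), rest = NA_real_))
  an <- data.frame(optode = 1:3, landmark = c("Fz", "Cz", "Pz"))
  probe_design(op, sp, an)
}

probe_minimal <- function() {
  op <- data.frame(x = c(0, 0, 0, -30, 0, 30),
                   y = c(60, 0, -60, 80, 85, 80),
                   z = c(60, 95, 60, 30, 35, 30),
                   kind = c("dummy", "dummy", "dummy", "source", "detector", "source"),
                   grommet = "#default", rotation = 0)
  sp <- data.frame(i = c(4, 5, 2), j = c(5, 6, 5), rest = c(30, 30, NA))
  an <- data.frame(optode = 1:3, landmark = c("Fz", "Cz", "Pz"))
  probe_design(op, sp, an)
}

# full pipeline run on the default fixture, shared by several tests
default_cap_run <- function() {
  cached("default_cap_run", {
    out <- file.path(tempdir(), "capgen_default_run")
    suppressWarnings(generate_cap("synthetic:56", probe_minimal(),
                                  cap_config(out_dir = out),
                                  keep_intermediates = TRUE))
  })
}

# constructed straight-seam comb fixture for tab tests: a rectangle
# with `n` lattice teeth reaching the seam at y = 0 (panel above if
# side = +1, below if side = -1)
comb_panel <- function(n, side = 1, role = "mid-front", grommets = NULL,
                       width_mm = 100, tooth = 8) {
  outline <- rbind(c(0, 0), c(width_mm, 0), c(width_mm, side * 40), c(0, side * 40))
  if (polygon_area(outline) < 0) outline <- outline[4:1, ]
  d <- panel_design_2d(role, outline, rep("axial", 4), grommets,
                       seams = list(test = list(poly = rbind(c(0, 0), c(width_mm, 0)),
                                                s = c(0, width_mm))))
  xs <- seq(width_mm / (n + 1), width_mm * n / (n + 1), length.out = n)
  nodes <- rbind(cbind(xs, 0),                    # seam contacts
                 cbind(xs, side * tooth),         # tooth roots
                 cbind(xs, side * 2 * tooth))     # spine anchors
  edges <- rbind(cbind(seq_len(n), n + seq_len(n)),
                 cbind(n + seq_len(n), 2 * n + seq_len(n)),
                 if (n > 1) cbind(2 * n + seq_len(n - 1), 2 * n + 1 + seq_len(n - 1)))
  # outline ring
  base <- nrow(nodes)
  nodes <- rbind(nodes, outline)
  ring <- cbind(base + 1:4, base + c(2, 3, 4, 1))
  edges <- rbind(edges, ring)
  d$lattice <- list(nodes = nodes, edges = edges,
                    width = c(rep(0.85, nrow(edges) - 4), rep(0.85, 4)),
                    kind = c(rep("hex", nrow(edges) - 4), rep("outline", 4)),
                    hex_edge = 10)
  d
}

# small vector helpers mirrored from the package internals
vnorm <- function(v) sqrt(sum(v^2))
row_norms <- function(m) sqrt(rowSums(m^2))
`%||%` <- function(a, b) if (is.null(a)) b else a
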