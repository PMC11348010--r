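#' Probe design: optodes, springs, anchors
#'
#' Container for a cap probe layout.  Optodes (sources, detectors and
#' dummies) carry a grommet identifier (`"#"` + name) and a rotation
#' about the local surface normal.  Springs are pairwise distance
#' constraints: rigid (fixed rest length in mm, a source-detector
#' separation) or flexible (free length, `rest = NA`).  Anchors bind an
#' optode to a 10-5 landmark, which it occupies exactly after
#' registration.
#'
#' @param optodes data.frame with columns `x`, `y`, `z` (design position,
#'   mm), `kind` (`"source"`, `"detector"` or `"dummy"`), `grommet`
#'   (`"#name"`), `rotation` (degrees, default 0).
#' @param springs data.frame with columns `i`, `j` (optode indices) and
#'   `rest` (mm; `NA` = flexible).
#' @param anchors data.frame with columns `optode` (index) and
#'   `landmark` (10-5 label).
#' @param measurements Optional source-detector channel list (carried
#'   through, unused for geometry).
#' @return Object of class `probe_design`.
#' @export
probe_design <- function(optodes, springs = NULL, anchors, measurements = NULL) {
  optodes <- as.data.frame(optodes)
  if (is.null(optodes$rotation)) optodes$rotation <- 0
  stopifnot(all(c("x", "y", "z", "kind", "grommet") %in% names(optodes)))
  if (!all(optodes$kind %in% c("source", "detector", "dummy")))
    stop("optode kind must be source, detector or dummy")
  if (any(!nzchar(optodes$grommet)) || any(substr(optodes$grommet, 1, 1) != "#"))
    stop("grommet ids must be non-empty and begin with '#'")
  if (is.null(springs)) springs <- data.frame(i = integer(), j = integer(), rest = numeric())
  springs <- as.data.frame(springs)
  anchors <- as.data.frame(anchors)
  stopifnot(all(c("optode", "landmark") %in% names(anchors)))
  structure(list(optodes = optodes, springs = springs, anchors = anchors,
                 measurements = measurements), class = "probe_design")
}

#' @export
print.probe_design <- function(x, ...) {
  cat(sprintf("<probe_design> %d optodes (%d springs, %d anchors)\n",
              nrow(x$optodes), nrow(x$springs), nrow(x$anchors)))
  invisible(x)
}

#' Read a probe design (JSON or AtlasViewer-style .SD MAT dialect)
#'
#' The MAT dialect expects a struct `SD` with `SrcPos`/`DetPos`/`DummyPos`
#' (n x 3, mm), `SpringList` (n x 3: two 1-based optode indices over the
#' concatenated source/detector/dummy list, then rest length in mm with
#' negative values meaning flexible), `AnchorList` (cell n x 2: optode
#' index, landmark label), `SrcGrommetType`/`DetGrommetType`/
#' `DummyGrommetType` (cells of `"#name"` strings, or a single string),
#' optional `*GrommetRot` and `MeasList`.  The JSON schema is the 1:1
#' mirror documented in [write_probe_json()].
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"json"` or `"sd-mat"`.
#' @return A [probe_design].
#' @export
read_probe_design <- function(path, format = c("auto", "json", "sd-mat")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(sd|mat)$", tolower(path))) "sd-mat" else "json"
  }
  if (format == "json") read_probe_json(path) else read_probe_sd(path)
}

read_probe_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("optodes", "anchors")) {
    if (is.null(j[[f]])) stop("probe JSON missing required field: ", f)
  }
  op <- do.call(rbind, lapply(j$optodes, function(o) {
    data.frame(x = o$pos[[1]], y = o$pos[[2]], z = o$pos[[3]],
               kind = o$kind, grommet = o$grommet,
               rotation = if (is.null(o$rotation)) 0 else o$rotation)
  }))
  sp <- if (length(j$springs)) do.call(rbind, lapply(j$springs, function(s) {
    data.frame(i = s$optodes[[1]], j = s$optodes[[2]],
               rest = if (is.null(s$rest)) NA_real_ else s$rest)
  })) else NULL
  an <- do.call(rbind, lapply(j$anchors, function(a) {
    data.frame(optode = a$optode, landmark = a$landmark)
  }))
  meas <- if (length(j$measurements))
    do.call(rbind, lapply(j$measurements, function(m) unlist(m))) else NULL
  probe_design(op, sp, an, meas)
}

#' Write a probe design as JSON
#'
#' Schema: `{"optodes": [{"pos": [x,y,z], "kind": "...", "grommet": "#..",
#' "rotation": deg}], "springs": [{"optodes": [i,j], "rest": mm|null}],
#' "anchors": [{"optode": i, "landmark": "Cz"}], "measurements": [[s,d],..]}`.
#' Flexible springs have `"rest": null`.
#'
#' @param probe A [probe_design].
#' @param path Output path.
#' @export
write_probe_json <- function(probe, path) {
  op <- lapply(seq_len(nrow(probe$optodes)), function(i) {
    o <- probe$optodes[i, ]
    list(pos = c(o$x, o$y, o$z), kind = o$kind, grommet = o$grommet,
         rotation = o$rotation)
  })
  sp <- lapply(seq_len(nrow(probe$springs)), function(k) {
    s <- probe$springs[k, ]
    list(optodes = c(s$i, s$j), rest = if (is.na(s$rest)) NULL else s$rest)
  })
  an <- lapply(seq_len(nrow(probe$anchors)), function(k) {
    a <- probe$anchors[k, ]
    list(optode = a$optode, landmark = a$landmark)
  })
  meas <- if (!is.null(probe$measurements))
    lapply(seq_len(nrow(probe$measurements)), function(i)
      as.numeric(probe$measurements[i, ])) else NULL
  jsonlite::write_json(list(optodes = op, springs = sp, anchors = an,
                            measurements = meas),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

read_probe_sd <- function(path) {
  vars <- read_mat(path)
  sd <- vars$SD
  if (is.null(sd)) stop("SD MAT-file missing required struct: SD")
  as3 <- function(m) if (is.null(m) || !length(m)) matrix(0, 0, 3)
                     else if (is.matrix(m)) m[, 1:3, drop = FALSE]
                     else matrix(m, ncol = 3)
  src <- as3(sd$SrcPos); det <- as3(sd$DetPos); dum <- as3(sd$DummyPos)
  grom <- function(field, n, default = "#default") {
    g <- sd[[field]]
    if (is.null(g)) rep(default, n)
    else if (is.character(g)) rep(g, n)
    else vapply(g, function(x) as.character(x), character(1))
  }
  rots <- function(field, n) {
    r <- sd[[field]]
    if (is.null(r)) rep(0, n) else as.numeric(r)
  }
  op <- data.frame(
    x = c(src[, 1], det[, 1], dum[, 1]),
    y = c(src[, 2], det[, 2], dum[, 2]),
    z = c(src[, 3], det[, 3], dum[, 3]),
    kind = c(rep("source", nrow(src)), rep("detector", nrow(det)),
             rep("dummy", nrow(dum))),
    grommet = c(grom("SrcGrommetType", nrow(src)),
                grom("DetGrommetType", nrow(det)),
                grom("DummyGrommetType", nrow(dum))),
    rotation = c(rots("SrcGrommetRot", nrow(src)),
                 rots("DetGrommetRot", nrow(det)),
                 rots("DummyGrommetRot", nrow(dum))))
  sp <- NULL
  if (!is.null(sd$SpringList) && length(sd$SpringList)) {
    sl <- if (is.matrix(sd$SpringList)) sd$SpringList else matrix(sd$SpringList, ncol = 3)
    rest <- sl[, 3]
    rest[rest < 0] <- NA_real_   # negative length encodes a flexible spring
    sp <- data.frame(i = as.integer(sl[, 1]), j = as.integer(sl[, 2]), rest = rest)
  }
  if (is.null(sd$AnchorList)) stop("SD MAT-file missing required field: AnchorList")
  al <- sd$AnchorList
  # cell n x 2 stored column-major: first n entries indices, next n labels
  n_anchor <- length(al) %/% 2
  an <- data.frame(
    optode = vapply(al[seq_len(n_anchor)], function(x) as.integer(x[1]), integer(1)),
    landmark = vapply(al[n_anchor + seq_len(n_anchor)], as.character, character(1)))
  meas <- if (!is.null(sd$MeasList) && length(sd$MeasList)) {
    ml <- if (is.matrix(sd$MeasList)) sd$MeasList else matrix(sd$MeasList, ncol = 2)
    ml[, 1:2, drop = FALSE]
  } else NULL
  probe_design(op, sp, an, meas)
}

#' Write a probe design in the .SD MAT dialect
#' @inheritParams write_probe_json
#' @export
write_probe_sd <- function(probe, path) {
  op <- probe$optodes
  pick <- function(k) as.matrix(op[op$kind == k, c("x", "y", "z")])
  idx_all <- seq_len(nrow(op))
  ord <- order(match(op$kind, c("source", "detector", "dummy")))
  remap <- match(idx_all, ord)   # old index -> SD index
  sl <- probe$springs
  sl_m <- if (nrow(sl)) cbind(remap[sl$i], remap[sl$j],
                              ifelse(is.na(sl$rest), -1, sl$rest))
          else matrix(0, 0, 3)
  an <- probe$anchors
  sd <- list(
    SrcPos = pick("source"), DetPos = pick("detector"), DummyPos = pick("dummy"),
    SrcGrommetType = as.list(op$grommet[op$kind == "source"]),
    DetGrommetType = as.list(op$grommet[op$kind == "detector"]),
    DummyGrommetType = as.list(op$grommet[op$kind == "dummy"]),
    SrcGrommetRot = op$rotation[op$kind == "source"],
    DetGrommetRot = op$rotation[op$kind == "detector"],
    DummyGrommetRot = op$rotation[op$kind == "dummy"],
    SpringList = sl_m,
    AnchorList = c(lapply(remap[an$optode], as.numeric), as.list(an$landmark)),
    MeasList = if (is.null(probe$measurements)) matrix(0, 0, 2)
               else as.matrix(probe$measurements))
  write_mat(list(SD = sd), path)
  attr(path, "index_map") <- remap
  invisible(path)
}

#' Validate a probe design against a landmark set
#'
#' Report-based: returns all violations rather than stopping at the
#' first.  Checks index ranges, rest lengths, anchor labels, duplicate
#' anchors, and that every optode is connected through the spring graph
#' to an anchored optode (registration is underdetermined otherwise).
#'
#' @param probe A [probe_design].
#' @param landmarks A `landmark_set` (or NULL to skip label checks).
#' @return data.frame with columns `code` and `detail`; zero rows iff valid.
#' @export
validate_probe <- function(probe, landmarks = NULL) {
  v <- list()
  bad <- function(code, detail) v[[length(v) + 1]] <<- data.frame(code = code, detail = detail)
  n <- nrow(probe$optodes)
  if (nrow(probe$anchors) == 0) bad("no-anchor", "probe has no anchors")
  sp <- probe$springs
  if (nrow(sp)) {
    dangling <- sp$i < 1 | sp$i > n | sp$j < 1 | sp$j > n
    for (k in which(dangling))
      bad("dangling-index", sprintf("spring %d references optode %d/%d of %d", k, sp$i[k], sp$j[k], n))
    for (k in which(!dangling & sp$i == sp$j))
      bad("self-spring", sprintf("spring %d connects optode %d to itself", k, sp$i[k]))
    for (k in which(!is.na(sp$rest) & sp$rest <= 0))
      bad("bad-rest-length", sprintf("spring %d has non-positive rest length", k))
  }
  an <- probe$anchors
  outr <- an$optode < 1 | an$optode > n
  for (k in which(outr))
    bad("dangling-index", sprintf("anchor %d references optode %d of %d", k, an$optode[k], n))
  dup <- duplicated(an$optode) & !outr
  for (k in which(dup))
    bad("duplicate-anchor", sprintf("optode %d has multiple anchors", an$optode[k]))
  if (!is.null(landmarks)) {
    known <- landmarks$positions$label
    for (k in which(!an$landmark %in% known))
      bad("unknown-landmark", sprintf("anchor %d: unknown landmark '%s'", k, an$landmark[k]))
  }
  # connectivity: every optode must reach an anchored optode via springs
  if (n > 0) {
    comp <- seq_len(n)
    find <- function(i) { i <- as.integer(i)
      while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
    if (nrow(sp)) for (k in which(sp$i >= 1 & sp$i <= n & sp$j >= 1 & sp$j <= n))
      comp[find(sp$i[k])] <- find(sp$j[k])
    roots <- vapply(seq_len(n), find, integer(1))
    anchored_roots <- unique(roots[an$optode[!outr]])
    for (i in which(!roots %in% anchored_roots))
      bad("unreachable-from-anchor", sprintf("optode %d is not connected to any anchored optode", i))
  }
  if (length(v)) do.call(rbind, v) else data.frame(code = character(), detail = character())
}

#' Register a probe onto a head surface by spring relaxation
#'
#' Anchored optodes are pinned exactly to their landmark positions; free
#' optodes iteratively move under Hookean forces of the rigid springs
#' (unit spring constant; flexible springs exert no force) and are
#' reprojected to their nearest surface point after every step.
#' Deterministic: simultaneous (Jacobi) update in optode-index order, no
#' randomness.
#'
#' @param probe A [probe_design] that passes [validate_probe()].
#' @param head A [head_mesh].
#' @param landmarks A `landmark_set` for the same head.
#' @param damping Force-to-displacement factor per iteration.
#' @param step_cap Maximum displacement per optode per iteration (mm).
#' @param conv_tol Stop when the largest optode displacement in one
#'   iteration falls below this (mm).
#' @param max_iters Iteration bound; exceeding it raises a convergence
#'   error carrying the residuals.
#' @return n x 3 matrix of registered optode positions with attributes
#'   `residual` (max rigid-spring length error, mm), `residual_history`
#'   and `iterations`.
#' @export
register_probe <- function(probe, head, landmarks, damping = 0.5,
                           step_cap = 2, conv_tol = 0.01, max_iters = 5000) {
  rep_ok <- validate_probe(probe, landmarks)
  if (nrow(rep_ok)) stop("invalid probe: ", paste(rep_ok$code, collapse = ", "))
  mesh <- if (inherits(head, "head_mesh")) head$mesh else head
  n <- nrow(probe$optodes)
  X <- as.matrix(probe$optodes[, c("x", "y", "z")])
  anchor_idx <- probe$anchors$optode
  anchor_pos <- landmark_positions(landmarks, probe$anchors$landmark)
  free <- setdiff(seq_len(n), anchor_idx)
  # initialization: rigid least-squares (Kabsch) of design positions onto
  # the anchors; with < 3 anchors fall back to centroid alignment
  if (length(anchor_idx) >= 3) {
    A <- X[anchor_idx, , drop = FALSE]
    B <- anchor_pos
    ca <- colMeans(A); cb <- colMeans(B)
    H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    X <- sweep(sweep(X, 2, ca) %*% t(R), 2, cb, `+`)
  } else {
    X <- sweep(X, 2, X[anchor_idx[1], ] - anchor_pos[1, ], `-`)
  }
  X[anchor_idx, ] <- anchor_pos
  if (length(free)) {
    pr <- nearest_on_mesh(mesh, X[free, , drop = FALSE])
    X[free, ] <- as.matrix(pr[, c("x", "y", "z")])
  }
  sp <- probe$springs
  rigid <- sp[!is.na(sp$rest), , drop = FALSE]
  resid_hist <- numeric(0)
  spring_resid <- function(X) {
    if (!nrow(rigid)) return(0)
    len <- sqrt(rowSums((X[rigid$i, , drop = FALSE] - X[rigid$j, , drop = FALSE])^2))
    max(abs(len - rigid$rest))
  }
  it <- 0
  repeat {
    it <- it + 1
    F <- matrix(0, n, 3)
    if (nrow(rigid)) {
      dvec <- X[rigid$j, , drop = FALSE] - X[rigid$i, , drop = FALSE]
      len <- pmax(sqrt(rowSums(dvec^2)), 1e-12)
      f <- (len - rigid$rest) / len
      for (k in seq_len(nrow(rigid))) {
        F[rigid$i[k], ] <- F[rigid$i[k], ] + f[k] * dvec[k, ]
        F[rigid$j[k], ] <- F[rigid$j[k], ] - f[k] * dvec[k, ]
      }
    }
    Xn <- X
    if (length(free)) {
      disp <- damping * F[free, , drop = FALSE]
      nrm <- sqrt(rowSums(disp^2))
      over <- nrm > step_cap
      disp[over, ] <- disp[over, , drop = FALSE] * (step_cap / nrm[over])
      Xn[free, ] <- X[free, , drop = FALSE] + disp
      pr <- nearest_on_mesh(mesh, Xn[free, , drop = FALSE])
      Xn[free, ] <- as.matrix(pr[, c("x", "y", "z")])
    }
    Xn[anchor_idx, ] <- anchor_pos
    moved <- if (length(free)) max(sqrt(rowSums((Xn[free, , drop = FALSE] -
                                                 X[free, , drop = FALSE])^2))) else 0
    X <- Xn
    resid_hist <- c(resid_hist, spring_resid(X))
    if (moved < conv_tol) break
    if (it >= max_iters) {
      stop(errorCondition(
        sprintf("probe registration did not converge in %d iterations (last displacement %.4f mm, spring residual %.3f mm)",
                max_iters, moved, spring_resid(X)),
        residual = spring_resid(X), history = resid_hist,
        class = c("capgen_convergence_error", "error", "condition")))
    }
  }
  rownames(X) <- NULL
  attr(X, "residual") <- spring_resid(X)
  attr(X, "residual_history") <- resid_hist
  attr(X, "iterations") <- it
  X
}
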