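# End-to-end orchestration: head -> landmarks -> probe registration ->
# embed -> cut -> flatten -> panel designs -> solids -> STL + report.

#' Cap generation configuration
#'
#' All printed geometric parameters of the pipeline with their published
#' defaults: hexagon edge 10 mm, lattice width 0.85 mm, welding tab
#' width 2 mm, extrusion thickness 0.9 mm, gravity step and Z tolerance
#' 0.1 mm, ear-slit offset 15 mm above the pre-auricular point, axial
#' cut 15 mm above nasion, mid panel spanning 3/7 of the coronal
#' ear-to-ear arc, tab search reach one hex edge, flattened-area
#' tolerance 5%.
#'
#' @param HC Head circumference, cm.
#' @param hex_edge,lattice_width,tab_width,extrude,gravity_step,z_tol,ear_slit_offset,axial_cut_offset,tab_reach
#'   Lengths in mm.
#' @param mid_fraction Ratio in (0, 1).
#' @param area_tol Ratio.
#' @param max_iters Flattening iteration bound.
#' @param grommet_dir Grommet library directory (NULL: generate a
#'   default library in a temporary directory).
#' @param out_dir Output directory.
#' @param ... Overrides passed as name = value.
#' @return List of class `cap_config`.
#' @export
cap_config <- function(HC = 56, hex_edge = 10, lattice_width = 0.85,
                       tab_width = 2, extrude = 0.9, gravity_step = 0.1,
                       z_tol = 0.1, ear_slit_offset = 15,
                       axial_cut_offset = 15, mid_fraction = 3 / 7,
                       tab_reach = 10, area_tol = 0.05, max_iters = 50000,
                       grommet_dir = NULL, out_dir = tempfile("cap_"), ...) {
  cfg <- list(HC = HC, hex_edge = hex_edge, lattice_width = lattice_width,
              tab_width = tab_width, extrude = extrude,
              gravity_step = gravity_step, z_tol = z_tol,
              ear_slit_offset = ear_slit_offset,
              axial_cut_offset = axial_cut_offset,
              mid_fraction = mid_fraction, tab_reach = tab_reach,
              area_tol = area_tol, max_iters = max_iters,
              grommet_dir = grommet_dir, out_dir = out_dir)
  cfg <- utils::modifyList(cfg, list(...))
  lens <- c("hex_edge", "lattice_width", "tab_width", "extrude",
            "gravity_step", "z_tol", "ear_slit_offset", "axial_cut_offset",
            "tab_reach")
  for (nm in lens) if (cfg[[nm]] <= 0) stop("config field must be positive: ", nm)
  if (cfg$HC <= 0) stop("config field must be positive: HC")
  if (cfg$mid_fraction <= 0 || cfg$mid_fraction >= 1)
    stop("mid_fraction must be in (0, 1)")
  structure(cfg, class = "cap_config")
}

#' Load a head model from file or synthetic specification
#'
#' @param source Either a path to an STL/OFF scalp mesh (with a JSON
#'   fiducial sidecar `<file>.fiducials.json` holding
#'   `{"Nz": [x,y,z], ...}`) or a string `"synthetic:HC,rx,ry,rz"` /
#'   a list with fields `circumference`, `axis_ratios`, `refinement`.
#' @param refinement Refinement for synthetic heads.
#' @return A [head_mesh].
#' @export
load_head <- function(source, refinement = 3) {
  if (inherits(source, "head_mesh")) return(source)
  if (is.list(source)) {
    return(synthetic_head(source$circumference %||% 56,
                          source$axis_ratios %||% c(1, 1.25, 1.1),
                          source$refinement %||% refinement))
  }
  if (grepl("^synthetic", source)) {
    spec <- sub("^synthetic:?", "", source)
    nums <- as.numeric(strsplit(spec, ",")[[1]])
    if (!length(nums) || anyNA(nums)) nums <- 56
    ratios <- if (length(nums) >= 4) nums[2:4] else c(1, 1.25, 1.1)
    return(synthetic_head(nums[1], ratios, refinement))
  }
  mesh <- if (grepl("\\.off$", tolower(source))) read_off(source) else read_stl(source)
  sidecar <- paste0(source, ".fiducials.json")
  if (!file.exists(sidecar))
    sidecar <- sub("\\.(stl|off)$", ".fiducials.json", source, ignore.case = TRUE)
  if (!file.exists(sidecar))
    stop("fiducial sidecar JSON not found for ", source)
  fid <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  head_mesh(mesh, lapply(fid, as.numeric))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a full cap: four printable panels plus a JSON report
#'
#' Runs the whole pipeline: (1) head model scaled to the target
#' circumference, (2) 10-5 landmark construction, (3) spring-relaxation
#' probe registration, (4) landmark/optode embedding, (5) axial +
#' sagittal cutting, (6) per-panel flattening, (7) outlines, hex
#' lattice, mid halving and welding tabs, (8) extrusion, grommets, ear
#' slits, strap holders, (9) STL + report output.  Deterministic for
#' fixed inputs and configuration.
#'
#' @param head_source See [load_head()].
#' @param probe A [probe_design] or path to a probe file.
#' @param config A [cap_config].
#' @param keep_intermediates Keep stage outputs in the returned object.
#' @return Invisibly, a list with `stl_paths` (named character(4)),
#'   `report` (the report list, also written to
#'   `<out_dir>/cap_report.json`) and, if requested, `intermediates`.
#' @export
generate_cap <- function(head_source, probe, config = cap_config(),
                         keep_intermediates = FALSE) {
  t_start <- Sys.time()
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message("[capgen] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s (hint: check the report log and stage inputs)",
                   name, conditionMessage(e)), call. = FALSE)
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  # (1) head
  head <- stage("headmodel", load_head(head_source))
  head <- stage("headmodel", scale_head(head, config$HC))
  say("head: %d vertices, HC %.1f cm", nrow(head$mesh$vertices),
      head_circumference(head) / 10)
  # (2) landmarks
  landmarks <- stage("landmarks", compute_10_5_landmarks(head))
  say("landmarks: %d 10-5 positions", nrow(landmarks$positions))
  # (3) probe
  if (is.character(probe)) probe <- stage("probe", read_probe_design(probe))
  rep_v <- validate_probe(probe, landmarks)
  if (nrow(rep_v))
    stop("stage 'probe' failed: invalid probe design: ",
         paste(unique(rep_v$code), collapse = ", "))
  reg <- stage("register", register_probe(probe, head, landmarks))
  say("probe: %d optodes registered, rigid-spring residual %.3f mm",
      nrow(reg), attr(reg, "residual"))
  # (4) embed
  emb <- stage("embed", embed_landmarks(head, landmarks))
  head <- emb$head; landmarks <- emb$landmarks
  opt_labels <- paste0("optode:", seq_len(nrow(reg)))
  head <- stage("embed", embed_points(head, reg, opt_labels))
  opt_ids <- attr(head, "embedded")
  # (5) cut
  panels <- stage("cut", cut_panels(head, landmarks, opt_ids,
                                    axial_offset = config$axial_cut_offset,
                                    mid_fraction = config$mid_fraction))
  say("cut: x0 = %.1f mm; panel faces L/M/R = %d/%d/%d", attr(panels, "x0"),
      nrow(panels$left$mesh$faces), nrow(panels$mid$mesh$faces),
      nrow(panels$right$mesh$faces))
  # (6) flatten
  flats <- list()
  reports <- list()
  for (nm in names(panels)) {
    fl <- stage("flatten", flatten_panel(panels[[nm]],
                                         gravity_step = config$gravity_step,
                                         z_tol = config$z_tol,
                                         max_iters = config$max_iters,
                                         area_tol = config$area_tol))
    fl <- canonicalize_flat(fl)
    flats[[nm]] <- fl
    reports[[nm]] <- distortion_report(fl)
    say("flatten %s: %d iters, max|Z| %.3f mm, area ratio %.3f", nm,
        fl$iterations, fl$maxz, reports[[nm]]$area_ratio)
  }
  # (7) panel designs
  grommets_of <- function(flat) {
    mk <- flat$markers
    sel <- grepl("^optode:", names(mk))
    if (!any(sel)) return(NULL)
    idx <- as.integer(sub("^optode:", "", names(mk)[sel]))
    data.frame(x = flat$xy[mk[sel], 1], y = flat$xy[mk[sel], 2],
               rotation = probe$optodes$rotation[idx],
               grommet = probe$optodes$grommet[idx],
               name = names(mk)[sel], stringsAsFactors = FALSE)
  }
  halves <- stage("panel2d", build_mid_outlines(flats$mid, grommets_of(flats$mid)))
  left_d <- stage("panel2d", build_side_outline(flats$left, grommets = grommets_of(flats$left)))
  right_d <- stage("panel2d", build_side_outline(flats$right, grommets = grommets_of(flats$right)))
  designs <- list(left = left_d, `mid-front` = halves$front,
                  `mid-back` = halves$back, right = right_d)
  designs <- lapply(designs, function(d)
    stage("panel2d", hex_fill(d, edge = config$hex_edge, width = config$lattice_width)))
  # (7b) tabs: midline + both sagittal seams
  tb <- stage("tabs", generate_weld_tabs(designs$`mid-front`, designs$`mid-back`,
                                         "midline", config$tab_width, config$tab_reach))
  designs$`mid-front` <- tb$panelA; designs$`mid-back` <- tb$panelB
  for (side in c("left", "right")) {
    seam <- paste0("sagittal-", side)
    for (half in c("mid-front", "mid-back")) {
      tb <- stage("tabs", generate_weld_tabs(designs[[side]], designs[[half]],
                                             seam, config$tab_width, config$tab_reach))
      designs[[side]] <- tb$panelA; designs[[half]] <- tb$panelB
    }
  }
  tab_table <- do.call(rbind, lapply(names(designs), function(nm) {
    t <- designs[[nm]]$tabs
    if (is.null(t) || !nrow(t)) return(NULL)
    cbind(panel = nm, t[, c("pair_id", "seam_x", "seam_y", "merged", "near_grommet")])
  }))
  say("tabs: %d total, %d merged pairs, %d near-grommet extensions",
      if (is.null(tab_table)) 0L else nrow(tab_table),
      if (is.null(tab_table)) 0L else sum(tab_table$merged),
      if (is.null(tab_table)) 0L else sum(tab_table$near_grommet))
  # (8) solids
  lib <- if (is.null(config$grommet_dir)) {
    make_default_grommet_library(file.path(config$out_dir, "grommets"),
                                 unique(probe$optodes$grommet))
  } else grommet_library(config$grommet_dir)
  solids <- list()
  for (nm in names(designs)) {
    s <- stage("solidify", extrude_panel(designs[[nm]], config$extrude))
    if (nm %in% c("left", "right")) {
      ear <- stage("solidify", ear_anchor_2d(flats[[nm]], head))
      s <- stage("solidify", add_ear_slit(s, ear$point,
                                          offset_up = max(config$ear_slit_offset - ear$drop, 2)))
      s <- stage("solidify", add_strap_holders(s))
    }
    s <- stage("solidify", place_grommets(s, library = lib))
    checks <- validate_solid(s, config$extrude)
    if (!all(checks))
      stop("stage 'solidify' failed: panel ", nm, " failed checks: ",
           paste(names(checks)[!checks], collapse = ", "))
    solids[[nm]] <- s
    say("solid %s: %d triangles, %.0f mm^3, watertight", nm,
        nrow(s$mesh$faces), mesh_volume(s$mesh))
  }
  # (9) output
  stl_paths <- setNames(file.path(config$out_dir, paste0("panel_", names(solids), ".stl")),
                        names(solids))
  for (nm in names(solids)) write_stl(solids[[nm]], stl_paths[[nm]])
  manifest <- do.call(rbind, lapply(names(solids), function(nm)
    cbind(panel = nm, solids[[nm]]$manifest)))
  report <- list(
    config = unclass(config),
    head = list(vertices = nrow(head$mesh$vertices),
                HC_mm = head_circumference(head)),
    registration = list(residual_mm = attr(reg, "residual"),
                        iterations = attr(reg, "iterations")),
    x0_mm = attr(panels, "x0"),
    distortion = reports,
    tabs = tab_table,
    grommets = manifest,
    panels = lapply(solids, function(s)
      list(triangles = nrow(s$mesh$faces), volume_mm3 = mesh_volume(s$mesh),
           checks = as.list(validate_solid(s, config$extrude)))),
    runtime_s = as.numeric(Sys.time() - t_start, units = "secs"),
    log = log)
  jsonlite::write_json(report, file.path(config$out_dir, "cap_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  say("done in %.1f s -> %s", report$runtime_s, config$out_dir)
  invisible(list(stl_paths = stl_paths, report = report,
                 intermediates = if (keep_intermediates)
                   list(head = head, landmarks = landmarks, registered = reg,
                        panels = panels, flats = flats, designs = designs,
                        solids = solids)))
}

# 2D anchor for the ear slit: the flattened boundary point closest (in
# 3D) to the LPA/RPA fiducial, plus its 3D distance to the fiducial
# (the axial cut removes the fiducial itself).
ear_anchor_2d <- function(flat, head) {
  fid <- head$fiducials[if (flat$role == "left") "LPA" else "RPA", ]
  be <- unique(as.vector(as.matrix(flat$boundary[, c("from", "to")])))
  p3 <- flat$panel_vertices_3d[be, , drop = FALSE]
  d <- sqrt(rowSums(sweep(p3, 2, fid)^2))
  i <- which.min(d)
  list(point = flat$xy[be[i], ], drop = d[i])
}

#' Verify a cap run: invariant suite over the report and panels
#'
#' @param result The list returned by [generate_cap()] (or a path to a
#'   `cap_report.json`).
#' @return data.frame of named checks with pass/fail and values;
#'   attribute `ok` is TRUE when all pass.
#' @export
verify_cap <- function(result) {
  report <- if (is.character(result)) jsonlite::read_json(result, simplifyVector = TRUE)
            else result$report
  checks <- list()
  add <- function(name, pass, value = NA) {
    checks[[length(checks) + 1]] <<- data.frame(check = name, pass = pass,
                                                value = as.character(value))
  }
  cfg <- report$config
  for (nm in names(report$distortion)) {
    dr <- report$distortion[[nm]]
    add(paste0("area_tol:", nm), abs(dr$area_ratio - 1) <= cfg$area_tol, dr$area_ratio)
    add(paste0("maxz:", nm), dr$maxz <= cfg$z_tol + 1e-9, dr$maxz)
    cres <- dr$coupling_resid_max %||% 0
    add(paste0("coupling:", nm), cres <= 0.2, cres)
  }
  if (!is.null(report$tabs) && length(report$tabs)) {
    tt <- as.data.frame(report$tabs)
    bij <- all(table(tt$pair_id) >= 1)
    add("tab_pairing", bij, nrow(tt))
  }
  pn <- report$panels
  for (nm in names(pn)) {
    add(paste0("watertight:", nm), isTRUE(pn[[nm]]$checks$watertight))
    add(paste0("volume:", nm), pn[[nm]]$volume_mm3 > 0, round(pn[[nm]]$volume_mm3))
  }
  out <- do.call(rbind, checks)
  attr(out, "ok") <- all(out$pass)
  out
}
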