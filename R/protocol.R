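# Protocol configuration (YAML, schema-versioned) and emission of the
# per-replica PLUMED-dialect input tree realizing the 8-replica bias table
# for real MD engines. Emission is byte-deterministic: no timestamps inside
# the protocol files; provenance lives in a sidecar.

PROTOCOL_SCHEMA_VERSION <- 1L

#' Protocol configuration for PLUMED emission
#'
#' Bundles the replica ladder, the CV definitions, the funnel geometry and
#' the bias parameters. The defaults are the real-system protocol values:
#' main OPES Explore BARRIER 100 kJ/mol / PACE 10000, multi-CV BARRIER
#' 3 kJ/mol / PACE 20000, MultiThermal PACE 100, exchanges every 1000 steps.
#' SIGMA for the main CVs must be supplied (named vector, or via
#' `sigma_source`, a COLVAR file of a short unbiased run) before emission.
#'
#' @param ladder a [ladder_config()]
#' @param cv_specs list of [cv_spec()]; labels must be unique and cover every
#'   label any bias roster references
#' @param funnel a [funnel_geometry()]; `dual = TRUE` emits two mirrored
#'   restraint blocks
#' @param barrier_main,barrier_multicv BARRIERs, kJ/mol
#' @param pace_main,pace_multicv,pace_multithermal PACEs, integration steps
#' @param sigma named per-CV SIGMA values (main CVs at least)
#' @param sigma_source optional COLVAR path used to derive missing sigmas
#' @param n_temps MultiThermal temperature-grid size
#' @return object of class `protocol_config`
#' @export
protocol_config <- function(ladder, cv_specs, funnel,
                            barrier_main = 100, barrier_multicv = 3,
                            pace_main = 10000L, pace_multicv = 20000L,
                            pace_multithermal = 100L,
                            sigma = NULL, sigma_source = NULL,
                            n_temps = 8L) {
  stopifnot(inherits(ladder, "ladder_config"),
            inherits(funnel, "funnel_geometry"),
            barrier_main > 0, barrier_multicv > 0,
            pace_main >= 1, pace_multicv >= 1, pace_multithermal >= 1)
  labs <- vapply(cv_specs, function(s) s$label, character(1))
  if (anyDuplicated(labs)) stop("CV labels must be unique within a ladder")
  used <- unique(unlist(lapply(ladder$replicas, function(r)
    c(r$main_cvs, unlist(r$aux_rosters)))))
  missing_lab <- setdiff(used, labs)
  if (length(missing_lab))
    stop("cv_specs missing definitions for: ",
         paste(missing_lab, collapse = ", "))
  structure(list(schema_version = PROTOCOL_SCHEMA_VERSION, ladder = ladder,
                 cv_specs = cv_specs, funnel = funnel,
                 barrier_main = barrier_main,
                 barrier_multicv = barrier_multicv,
                 pace_main = as.integer(pace_main),
                 pace_multicv = as.integer(pace_multicv),
                 pace_multithermal = as.integer(pace_multithermal),
                 sigma = sigma, sigma_source = sigma_source,
                 n_temps = as.integer(n_temps)),
            class = "protocol_config")
}

#' Write a protocol configuration as YAML
#'
#' @param config a [protocol_config()]
#' @param path output path
#' @return path, invisibly
#' @export
write_protocol_config <- function(config, path) {
  lad <- config$ladder
  obj <- list(
    schema_version = config$schema_version,
    thermostat_T = lad$thermostat_T,
    exchange_stride = lad$exchange_stride,
    steps = lad$steps, seed = lad$seed,
    replicas = lapply(lad$replicas, function(r) list(
      index = r$index, main_cvs = as.list(r$main_cvs),
      aux_rosters = lapply(r$aux_rosters, as.list),
      multithermal_Tmax = r$multithermal_Tmax)),
    cv_specs = lapply(config$cv_specs, function(s) list(
      kind = s$kind, label = s$label,
      atom_selector = as.list(s$atom_selector),
      period = s$period, point = if (!is.null(s$point)) as.list(s$point),
      params = if (!is.null(s$params)) unclass(s$params))),
    funnel = unclass(config$funnel),
    barrier_main = config$barrier_main,
    barrier_multicv = config$barrier_multicv,
    pace_main = config$pace_main, pace_multicv = config$pace_multicv,
    pace_multithermal = config$pace_multithermal,
    n_temps = config$n_temps,
    sigma = if (!is.null(config$sigma)) as.list(config$sigma),
    sigma_source = config$sigma_source)
  writeLines(yaml::as.yaml(obj), path)
  invisible(path)
}

#' Read a protocol configuration from YAML
#'
#' @param path YAML path
#' @return a [protocol_config()]
#' @export
read_protocol_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$schema_version) || y$schema_version != PROTOCOL_SCHEMA_VERSION)
    stop("unsupported protocol config schema version: ",
         y$schema_version %||% "<missing>")
  reps <- lapply(y$replicas, function(r)
    replica_spec(r$index, main_cvs = unlist(r$main_cvs),
                 aux_rosters = lapply(r$aux_rosters, unlist),
                 multithermal_Tmax = r$multithermal_Tmax))
  lad <- ladder_config(reps, exchange_stride = y$exchange_stride,
                       steps = y$steps, seed = y$seed,
                       thermostat_T = y$thermostat_T)
  cvs <- lapply(y$cv_specs, function(s) {
    p <- if (!is.null(s$params)) do.call(coordination_params, s$params)
    cv_spec(s$kind, atom_selector = unlist(s$atom_selector) %||% integer(0),
            params = p, label = s$label, period = s$period,
            point = if (!is.null(s$point)) unlist(s$point))
  })
  fun <- funnel_geometry(origin = unlist(y$funnel$origin),
                         axis = unlist(y$funnel$axis),
                         cylinder_radius = y$funnel$cylinder_radius,
                         cone_half_angle = y$funnel$cone_half_angle,
                         cone_to_cylinder_z = y$funnel$cone_to_cylinder_z,
                         wall_spring_constant = y$funnel$wall_spring_constant,
                         dual = y$funnel$dual)
  protocol_config(lad, cvs, fun,
                  barrier_main = y$barrier_main,
                  barrier_multicv = y$barrier_multicv,
                  pace_main = y$pace_main, pace_multicv = y$pace_multicv,
                  pace_multithermal = y$pace_multithermal,
                  sigma = if (!is.null(y$sigma)) unlist(y$sigma),
                  sigma_source = y$sigma_source,
                  n_temps = y$n_temps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmtnum <- function(x) {
  # deterministic, locale-independent number formatting for emitted files
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == round(v) && abs(v) < 1e15) sprintf("%d", as.integer(round(v)))
    else sprintf("%.6g", v)
  }, character(1))
}

cv_block <- function(spec, funnel) {
  lab <- spec$label
  sel <- paste(spec$atom_selector, collapse = ",")
  switch(spec$kind,
    z_projection = c(
      sprintf("lig: COM ATOMS=%s", sel),
      sprintf("fo_%s: FIXEDATOM AT=%s", lab,
              paste(fmtnum(funnel$origin), collapse = ",")),
      sprintf("d_%s: DISTANCE ATOMS=fo_%s,lig COMPONENTS", lab, lab),
      sprintf("%s: COMBINE ARG=d_%s.x,d_%s.y,d_%s.z COEFFICIENTS=%s PERIODIC=NO",
              lab, lab, lab, lab,
              paste(fmtnum(funnel$axis), collapse = ","))),
    cos_orientation = c(
      sprintf("ax_%s: DISTANCE ATOMS=%s COMPONENTS", lab, sel),
      sprintf("n_%s: CUSTOM ARG=ax_%s.x,ax_%s.y,ax_%s.z FUNC=sqrt(x*x+y*y+z*z) PERIODIC=NO",
              lab, lab, lab, lab),
      sprintf("%s: CUSTOM ARG=ax_%s.x,ax_%s.y,ax_%s.z,n_%s FUNC=(x*%s+y*%s+z*%s)/t VAR=x,y,z,t PERIODIC=NO",
              lab, lab, lab, lab, lab,
              fmtnum(funnel$axis[1]), fmtnum(funnel$axis[2]),
              fmtnum(funnel$axis[3]))),
    coordination_WL = coordination_block(spec, sel),
    coordination_WH = c(
      sprintf("vp_%s: FIXEDATOM AT=%s", lab,
              paste(fmtnum(spec$point %||% funnel$origin), collapse = ",")),
      coordination_block(spec, sprintf("vp_%s", lab))),
    torsion = sprintf("%s: TORSION ATOMS=%s", lab, sel),
    coordinate = sprintf("# %s: toy-engine coordinate CV (no PLUMED block)",
                         lab))
}

coordination_block <- function(spec, groupa) {
  p <- spec$params
  sprintf(paste0("%s: COORDINATION GROUPA=%s GROUPB=@water_oxygens ",
                 "SWITCH={RATIONAL R_0=%s D_MAX=%s NN=%d MM=%d} ",
                 "NLIST NL_CUTOFF=%s NL_STRIDE=%d"),
          spec$label, groupa, fmtnum(p$r0), fmtnum(p$d_max), p$n, p$m,
          fmtnum(p$r_nl), p$nl_update_stride)
}

funnel_blocks <- function(funnel) {
  mk <- function(suffix, axis_sign) {
    ax <- funnel$axis * axis_sign
    c(sprintf("fc_%s: FIXEDATOM AT=%s", suffix,
              paste(fmtnum(funnel$origin), collapse = ",")),
      sprintf("fd_%s: DISTANCE ATOMS=fc_%s,lig COMPONENTS", suffix, suffix),
      sprintf("fz_%s: COMBINE ARG=fd_%s.x,fd_%s.y,fd_%s.z COEFFICIENTS=%s PERIODIC=NO",
              suffix, suffix, suffix, suffix,
              paste(fmtnum(ax), collapse = ",")),
      sprintf("frho_%s: CUSTOM ARG=fd_%s.x,fd_%s.y,fd_%s.z,fz_%s FUNC=sqrt(x*x+y*y+z*z-t*t) VAR=x,y,z,t PERIODIC=NO",
              suffix, suffix, suffix, suffix, suffix),
      sprintf("fexc_%s: CUSTOM ARG=frho_%s,fz_%s FUNC=y-(%s+%s*max(0,%s-x)) VAR=y,x PERIODIC=NO",
              suffix, suffix, suffix, fmtnum(funnel$cylinder_radius),
              fmtnum(tan(funnel$cone_half_angle)),
              fmtnum(funnel$cone_to_cylinder_z)),
      sprintf("fwall_%s: UPPER_WALLS ARG=fexc_%s AT=0 KAPPA=%s EXP=2 LABEL_SUFFIX=%s",
              suffix, suffix, fmtnum(funnel$wall_spring_constant), suffix))
  }
  if (funnel$dual) c(mk("a", +1), mk("b", -1)) else mk("a", +1)
}

#' Emit the per-replica PLUMED-dialect input tree
#'
#' Creates one `replica-<k>/plumed.dat` per replica containing, in order: CV
#' definition blocks, the funnel restraint block(s) (two mirrored blocks for
#' a dual funnel), the main OPES Explore block on the main CVs with
#' BARRIER/PACE/SIGMA, the replica's multi-CV blocks, and a MultiThermal
#' block on replicas that carry one. Output is byte-deterministic; the
#' config itself is written alongside as `protocol.yaml` (the provenance
#' sidecar). Refuses to emit when SIGMA for a main CV or the funnel geometry
#' is missing.
#'
#' @param config a [protocol_config()]
#' @param out_dir output directory (created)
#' @return character vector of written plumed.dat paths, invisibly
#' @export
emit_plumed_protocol <- function(config, out_dir) {
  stopifnot(inherits(config, "protocol_config"))
  if (is.null(config$funnel)) stop("missing funnel geometry: refusing to emit")
  sigma <- config$sigma
  if (is.null(sigma) && !is.null(config$sigma_source)) {
    traj <- read_colvar(config$sigma_source)
    main_labs <- unique(unlist(lapply(config$ladder$replicas,
                                      function(r) r$main_cvs)))
    sigma <- compute_sigma_from_unbiased(traj, main_labs)
  }
  main_labs <- unique(unlist(lapply(config$ladder$replicas,
                                    function(r) r$main_cvs)))
  if (is.null(sigma) || !all(main_labs %in% names(sigma)))
    stop("missing SIGMA for main CV(s): refusing to emit (derive it from an ",
         "unbiased run, see compute_sigma_from_unbiased)")
  labs <- vapply(config$cv_specs, function(s) s$label, character(1))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (r in config$ladder$replicas) {
    dir <- file.path(out_dir, sprintf("replica-%d", r$index))
    dir.create(dir, showWarnings = FALSE)
    lines <- c(
      "# OneOPES replica input (PLUMED 2.9 dialect)",
      sprintf("# replica %d of %d", r$index,
              length(config$ladder$replicas)),
      "# Funnel restraint composition: axial projection fz and radial",
      "# distance frho from the funnel origin; allowed radius",
      "# R(z) = Rcyl + tan(alpha)*max(0, zcc - z); harmonic UPPER_WALLS on",
      "# the radial excess. Mirrored '_b' blocks appear for dual funnels.",
      "UNITS LENGTH=nm ENERGY=kj/mol",
      "")
    used_here <- unique(c(r$main_cvs, unlist(r$aux_rosters)))
    for (lab in used_here) {
      spec <- config$cv_specs[[match(lab, labs)]]
      lines <- c(lines, cv_block(spec, config$funnel), "")
    }
    lines <- c(lines, funnel_blocks(config$funnel), "")
    lines <- c(lines, sprintf(
      "opes_main: OPES_METAD_EXPLORE ARG=%s PACE=%d BARRIER=%s SIGMA=%s TEMP=%s",
      paste(r$main_cvs, collapse = ","), config$pace_main,
      fmtnum(config$barrier_main),
      paste(fmtnum(unname(sigma[r$main_cvs])), collapse = ","),
      fmtnum(config$ladder$thermostat_T)))
    for (i in seq_along(r$aux_rosters)) {
      ro <- r$aux_rosters[[i]]
      sig <- vapply(ro, function(l)
        if (l %in% names(sigma)) sigma[[l]] else NA_real_, numeric(1))
      sig_kw <- if (anyNA(sig)) "" else
        sprintf(" SIGMA=%s", paste(fmtnum(unname(sig)), collapse = ","))
      lines <- c(lines, sprintf(
        "opes_multicv%d: OPES_METAD_EXPLORE ARG=%s PACE=%d BARRIER=%s%s TEMP=%s",
        i, paste(ro, collapse = ","), config$pace_multicv,
        fmtnum(config$barrier_multicv), sig_kw,
        fmtnum(config$ladder$thermostat_T)))
    }
    if (!is.null(r$multithermal_Tmax)) {
      lines <- c(lines, "ene: ENERGY", sprintf(
        "opes_multit: OPES_EXPANDED ARG=ecv.* PACE=%d # ECV_MULTITHERMAL TEMP_MIN=%s TEMP_MAX=%s TEMP_STEPS=%d ARG=ene",
        config$pace_multithermal,
        fmtnum(config$ladder$thermostat_T),
        fmtnum(r$multithermal_Tmax), config$n_temps))
    }
    lines <- c(lines, "",
               sprintf("PRINT ARG=%s,*.bias STRIDE=500 FILE=COLVAR",
                       paste(used_here, collapse = ",")))
    path <- file.path(dir, "plumed.dat")
    writeLines(lines, path)
    paths <- c(paths, path)
    writeLines(mdp_template(), file.path(dir, "gromacs.mdp.template"))
  }
  write_protocol_config(config, file.path(out_dir, "protocol.yaml"))
  invisible(paths)
}

mdp_template <- function() {
  c("; GROMACS run-parameter template (commented; running MD is out of scope)",
    "; integrator  = md        ; leapfrog",
    "; dt          = 0.002     ; 2 fs with LINCS on hydrogen stretches",
    "; tcoupl      = V-rescale ; 298 K thermostat",
    "; pcoupl      = C-rescale ; 1 bar barostat",
    "; coulombtype = PME       ; rvdw = 1.0 nm")
}

#' Static dependency check of an emitted PLUMED file
#'
#' Verifies that every CV label referenced by a bias block's ARG list is
#' defined earlier in the same file.
#'
#' @param path plumed.dat path
#' @return TRUE (invisibly) or an error naming the first undefined label
#' @export
check_plumed_file <- function(path) {
  lines <- readLines(path)
  defined <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*#", ln) || !nzchar(trimws(ln))) next
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+):", ln))[[1]]
    args <- regmatches(ln, regexec("ARG=([^ ]+)", ln))[[1]]
    if (length(args) == 2 && !grepl("\\*", args[2])) {
      for (a in strsplit(args[2], ",")[[1]]) {
        base <- sub("\\..*$", "", a)
        if (!(base %in% defined))
          stop(sprintf("undefined label '%s' referenced at line %d of %s",
                       a, i, path))
      }
    }
    if (length(m) == 2) defined <- c(defined, m[2])
  }
  invisible(TRUE)
}

#' Shipped example protocol configuration
#'
#' A complete dual-funnel, three-torsion configuration of the default
#' 8-replica ladder, with all protocol parameters at their real-system
#' values. Used for the golden-file emission tests and as a CLI starting
#' point; the atom indices are illustrative.
#'
#' @return a [protocol_config()]
#' @export
example_protocol_config <- function() {
  lad <- build_default_ladder(torsions = c("t1", "t2", "t3"))
  cvs <- c(
    list(cv_spec("z_projection", 1:5, label = "z"),
         cv_spec("cos_orientation", c(1L, 5L), label = "COS"),
         cv_spec("torsion", 1:4, label = "t1"),
         cv_spec("torsion", 2:5, label = "t2"),
         cv_spec("torsion", 3:6, label = "t3")),
    lapply(c("WL4", "WL1"), function(l) cv_spec("coordination_WL", 2L,
                                                label = l)),
    lapply(c("WH1", "WH3", "WH8", "WH5", "WH10"), function(l)
      cv_spec("coordination_WH", label = l, point = c(0, 0, 0.1))))
  fun <- funnel_geometry(cylinder_radius = 0.2, cone_half_angle = 0.6,
                         cone_to_cylinder_z = 0.4,
                         wall_spring_constant = 1000, dual = TRUE)
  protocol_config(lad, cvs, fun, sigma = c(z = 0.05, COS = 0.1))
}
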