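# Pipeline driver: run every analysis stage for one or more states (e.g.
# bound and free forms of the same protein) from a single configuration, and
# compare states (delta-RMSF, helix profiles, accessibility). Every output
# table carries a header with the criteria that produced it, so reports are
# self-describing.

default_config <- function() {
  list(
    output_dir = "pepdyn_out",
    selection = list(atom_names = "CA"),
    windows = list(full = "full", first_half = "first_half",
                   second_half = "second_half"),
    residue_range = NULL,
    sites = integer(0),
    contacts = list(d_da_max = 3.5, angle_max = 30, salt_d_max = 4.0,
                    min_occupancy = 0.10, min_replicas = 2L,
                    chain_pair = NULL),
    sasa = list(probe_radius = 1.4, n_sphere_points = 960L, threshold = 20),
    seed = 1L)
}

#' Load a pipeline configuration
#'
#' Reads a YAML or JSON run configuration and fills in defaults. The
#' configuration names at least one state, each with a list of replica
#' trajectory files (multi-model PDB).
#'
#' @param config a file path (YAML/JSON) or a list.
#' @return validated config list (class `pepdyn_config`).
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON file")
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$states) || length(cfg$states) < 1L)
    stop("config must define at least one state under 'states'")
  for (st in names(cfg$states)) {
    paths <- cfg$states[[st]]$replicas
    if (is.null(paths) || length(paths) < 1L)
      stop("state '", st, "' defines no replica trajectories")
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0)
      stop("state '", st, "' references missing file(s): ",
           paste(missing, collapse = ", "))
  }
  class(cfg) <- c("pepdyn_config", "list")
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

state_setting <- function(cfg, state, key) {
  v <- cfg$states[[state]][[key]]
  if (is.null(v)) cfg[[key]] else v
}

#' Run the full analysis pipeline
#'
#' For every configured state: per-window RMSF profiles, helix-formation
#' probabilities, secondary-structure timelines, minimum-distance matrices,
#' interface contact occupancy with the persistence filter (states with at
#' least two chains), and site solvent-accessibility reports. When both a
#' `bound` and a `free` state are present, per-residue delta-RMSF
#' (free - bound) is computed; residue numbering must agree exactly between
#' the two states (mismatches are an error, never silently intersected).
#'
#' @param config a config list or YAML/JSON path (see [load_config()]).
#' @return object of class `pepdyn_report`: list with `states` (per-state
#'   results), `comparison` (delta-RMSF etc. or `NULL`), `config`, `files`
#'   (all tables written).
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  meta0 <- list(config_hash = hash)
  files <- character(0)
  emit <- function(df, name, meta = list()) {
    p <- file.path(out_dir, name)
    write_report_tsv(df, p, meta = c(meta0, meta))
    files <<- c(files, p)
    p
  }

  sel <- with_stage("selection", do.call(selection_spec, cfg$selection))
  radii <- radii_set(probe_radius = cfg$sasa$probe_radius,
                     n_sphere_points = cfg$sasa$n_sphere_points)

  states <- list()
  for (st in names(cfg$states)) {
    res <- list()
    ens <- with_stage(paste0(st, ":read"), {
      read_ensemble(cfg$states[[st]]$replicas)
    })
    res$ensemble <- ens

    res$rmsf <- list()
    for (w in names(cfg$windows)) {
      prof <- with_stage(paste0(st, ":rmsf:", w), {
        rmsf(ens, sel, window = cfg$windows[[w]], label = w)
      })
      res$rmsf[[w]] <- prof
      emit(as.data.frame(prof), sprintf("rmsf_%s_%s.tsv", st, w),
           list(state = st, window = w, units = "Angstrom"))
    }

    res$timeline <- with_stage(paste0(st, ":sse_timeline"), sse_timeline(ens))
    for (r in seq_along(res$timeline)) {
      m <- res$timeline[[r]]
      df <- data.frame(residue = rownames(m), as.data.frame(m), check.names = FALSE)
      emit(df, sprintf("sse_timeline_%s_rep%d.tsv", st, r),
           list(state = st, replica = r))
    }

    res$helix <- with_stage(paste0(st, ":helix_probability"), {
      helix_probability(ens, timeline = res$timeline)
    })
    emit(as.data.frame(res$helix), sprintf("helix_profile_%s.tsv", st),
         list(state = st, helix_states = "H"))

    rng <- state_setting(cfg, st, "residue_range")
    res$distmat <- with_stage(paste0(st, ":distance_matrix"), {
      min_distance_matrix(ens, residue_range = rng)
    })
    dm <- as.data.frame(res$distmat)
    dm <- cbind(residue = rownames(res$distmat), dm)
    emit(dm, sprintf("distmat_%s.tsv", st),
         list(state = st, statistic = attr(res$distmat, "statistic")))

    chains <- unique(ens$topology$atoms$chain_id)
    if (length(chains) >= 2L) {
      crit <- persistence_criteria(cfg$contacts$min_occupancy,
                                   cfg$contacts$min_replicas)
      res$contacts <- with_stage(paste0(st, ":contacts"), {
        hb <- contact_occupancy(ens, "hbond",
                                d_da_max = cfg$contacts$d_da_max,
                                angle_max = cfg$contacts$angle_max)
        sb <- contact_occupancy(ens, "saltbridge",
                                d_max = cfg$contacts$salt_d_max)
        all_rec <- rbind(as.data.frame(hb), as.data.frame(sb))
        class(all_rec) <- c("contact_records", "data.frame")
        attr(all_rec, "n_frames") <- attr(hb, "n_frames")
        persistence_filter(all_rec, crit)
      })
      geom_meta <- list(d_da_max = cfg$contacts$d_da_max,
                        angle_max = cfg$contacts$angle_max,
                        salt_d_max = cfg$contacts$salt_d_max,
                        min_occupancy = crit$min_occupancy,
                        min_replicas = crit$min_replicas)
      ann <- attr(res$contacts, "annotated")
      ann$persistent <- ifelse(ann$persistent, "Y", "N")
      emit(ann, sprintf("contacts_%s.tsv", st), c(list(state = st), geom_meta))
      pair <- cfg$contacts$chain_pair
      if (is.null(pair)) pair <- chains[1:2]
      res$interface <- with_stage(paste0(st, ":interface_table"), {
        interface_table(res$contacts, pair, known_chains = chains)
      })
      emit(res$interface, sprintf("interface_%s.tsv", st),
           c(list(state = st, chain_pair = paste(pair, collapse = "-")),
             geom_meta))
    }

    sites <- state_setting(cfg, st, "sites")
    if (length(sites) > 0) {
      res$accessibility <- with_stage(paste0(st, ":accessibility"), {
        site_accessibility_report(ens, sites, radii = radii,
                                  threshold = cfg$sasa$threshold, state = st)
      })
      emit(as.data.frame(res$accessibility),
           sprintf("accessibility_%s.tsv", st),
           list(state = st, probe_radius = radii$probe_radius,
                n_sphere_points = radii$n_sphere_points,
                burial_threshold_percent = cfg$sasa$threshold))
    }
    states[[st]] <- res
  }

  comparison <- NULL
  if (all(c("bound", "free") %in% names(states))) {
    comparison <- with_stage("comparison", {
      cmp <- list()
      for (w in names(cfg$windows)) {
        b <- states$bound$rmsf[[w]]
        f <- states$free$rmsf[[w]]
        if (!identical(b[, c("chain_id", "res_seq", "res_name")],
                       f[, c("chain_id", "res_seq", "res_name")]))
          stop("residue numbering differs between bound and free states")
        d <- b[, c("chain_id", "res_seq", "res_name")]
        d$rmsf_bound <- b$rmsf_mean
        d$rmsf_free <- f$rmsf_mean
        d$delta_rmsf <- f$rmsf_mean - b$rmsf_mean
        cmp[[w]] <- d
        emit(d, sprintf("delta_rmsf_%s.tsv", w),
             list(window = w, delta = "free - bound", units = "Angstrom"))
      }
      acc <- lapply(states[c("bound", "free")], function(s) s$accessibility)
      acc <- acc[!vapply(acc, is.null, logical(1))]
      if (length(acc) > 0) {
        both <- do.call(rbind, lapply(acc, as.data.frame))
        rownames(both) <- NULL
        emit(both, "accessibility_comparison.tsv",
             list(burial_threshold_percent = cfg$sasa$threshold))
        cmp$accessibility <- both
      }
      cmp$helix <- lapply(states[c("bound", "free")], function(s) s$helix)
      cmp
    })
  }

  report <- structure(list(states = states, comparison = comparison,
                           config = cfg, config_hash = hash, files = files),
                      class = "pepdyn_report")
  # drop the raw coordinate arrays from the saved copy (tables only)
  slim <- report
  for (st in names(slim$states)) slim$states[[st]]$ensemble <- NULL
  saveRDS(slim, file.path(out_dir, "report.rds"))
  report
}

#' @export
print.pepdyn_report <- function(x, ...) {
  cat("pepdyn_report (config", substr(x$config_hash, 1L, 8L), ")\n")
  for (st in names(x$states)) {
    s <- x$states[[st]]
    cat("  state", st, ":", length(s$rmsf), "rmsf windows;",
        if (!is.null(s$contacts)) paste0(nrow(s$contacts), " persistent contacts;") else "",
        if (!is.null(s$accessibility)) paste0(nrow(s$accessibility), " sites") else "",
        "\n")
  }
  if (!is.null(x$comparison)) cat("  bound/free comparison present\n")
  cat("  ", length(x$files), "tables written\n")
  invisible(x)
}

#' Re-render the report tables of a finished pipeline run
#'
#' Reads `report.rds` from a pipeline output directory and rewrites every
#' TSV table (useful after manual deletion or for regenerating reports with
#' the same numbers).
#'
#' @param dir pipeline output directory.
#' @return the `pepdyn_report`, invisibly.
#' @export
rerender_report <- function(dir) {
  rds <- file.path(dir, "report.rds")
  if (!file.exists(rds)) stop("no report.rds in ", dir)
  report <- readRDS(rds)
  cfg <- report$config
  cfg$output_dir <- dir
  run_pipeline(cfg)
}
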