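# Formats: ASCII PLY meshes, JSON network state, CSV time series, YAML
# configuration, JSON run manifests. All round-trips are lossless (17
# significant digits).

fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a membrane mesh as PLY
#'
#' ASCII PLY with full double precision; readable by generic mesh viewers.
#'
#' @param mesh A `membrane_mesh` (or list with `V`, `F`).
#' @param path Output file.
#' @return `write_ply`: the path, invisibly. `read_ply`: list(V, F).
#' @export
write_ply <- function(mesh, path) {
  V <- mesh$V; F <- mesh$F
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0", "comment cortosim membrane mesh",
    paste("element vertex", nrow(V)),
    "property double x", "property double y", "property double z",
    paste("element face", nrow(F)),
    "property list uchar int vertex_indices", "end_header"), con)
  writeLines(paste(fmt17(V[, 1]), fmt17(V[, 2]), fmt17(V[, 3])), con)
  writeLines(paste(3, F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  endh <- which(lines == "end_header")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  vl <- lines[endh + seq_len(nv)]
  V <- do.call(rbind, lapply(strsplit(trimws(vl), "[[:space:]]+"),
                             as.numeric))
  fl <- lines[endh + nv + seq_len(nf)]
  F <- do.call(rbind, lapply(strsplit(trimws(fl), "[[:space:]]+"),
                             function(z) as.integer(z[2:4]) + 1L))
  list(V = V, F = F)
}

#' Write / read a full simulation snapshot
#'
#' The mesh goes to `<stem>.ply`, the network (filaments, cross-linkers,
#' motors, pool, clock, event log, rng-relevant metadata) to `<stem>.json`.
#' Round-trips are bit-exact on coordinates.
#'
#' @param state A simulation state.
#' @param stem Path stem (without extension).
#' @return `write_snapshot`: the stem, invisibly. `read_snapshot`: a state.
#' @export
write_snapshot <- function(state, stem) {
  write_ply(state$mesh, paste0(stem, ".ply"))
  payload <- list(
    format_version = 1L,
    time = state$time,
    params = unclass(state$params),
    region = attr(state, "region"),
    x = state$x, fil_id = state$fil_id, seg_rest = state$seg_rest,
    acps = state$acps,
    acp_free_bindable = state$acp_free_bindable,
    acp_free_plain = state$acp_free_plain,
    motor_ends = state$motors$ends, motor_df = state$motors$df,
    ref_area = state$mesh$ref_area, ref_volume = state$mesh$ref_volume,
    mesh_radius = state$mesh$radius,
    pool = state$pool, budget = state$budget,
    events = state$events)
  jsonlite::write_json(payload, paste0(stem, ".json"), digits = I(17),
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(stem)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(stem) {
  ply <- read_ply(paste0(stem, ".ply"))
  js <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (is.null(js$format_version) || js$format_version != 1L) {
    stop("snapshot format version mismatch")
  }
  p <- js$params
  class(p) <- "sim_params"
  mesh <- structure(list(V = ply$V, F = ply$F), class = "membrane_mesh")
  mesh$edges <- mesh_edges(ply$F)
  mesh$ref_area <- js$ref_area
  mesh$ref_volume <- js$ref_volume
  mesh$radius <- js$mesh_radius
  state <- new_state(p, mesh, pool = js$pool, budget = js$budget)
  if (length(js$x)) {
    state$x <- matrix(js$x, ncol = 3)
    state$fil_id <- as.integer(js$fil_id)
    state$seg_rest <- as.numeric(js$seg_rest)
  }
  if (!is.null(js$acps) && NROW(js$acps)) {
    a <- as.data.frame(js$acps)
    a$f1 <- as.integer(a$f1); a$f2 <- as.integer(a$f2)
    a$a_face <- as.integer(a$a_face)
    state$acps <- a
  }
  state$acp_free_bindable <- js$acp_free_bindable
  state$acp_free_plain <- js$acp_free_plain
  if (length(js$motor_ends)) {
    state$motors$ends <- matrix(js$motor_ends, ncol = 3)
    m <- as.data.frame(js$motor_df)
    m$h1_fil <- as.integer(m$h1_fil); m$h2_fil <- as.integer(m$h2_fil)
    state$motors$df <- m
  }
  if (!is.null(js$events) && NROW(js$events)) {
    state$events <- as.data.frame(js$events)
  }
  state$time <- js$time
  if (!is.null(js$region)) attr(state, "region") <- js$region
  state
}

#' Write a measurement time series as CSV
#'
#' Deterministic column order `t, T_net_global, T_mem_global, volume,
#' n_blebs, max_bleb_diameter, Lmax_over_Dinit`; numbers carry 17
#' significant digits so values round-trip exactly.
#'
#' @param samples Data frame (e.g. `trajectory$series`).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_timeseries <- function(samples, path) {
  cols <- c("t", "T_net_global", "T_mem_global", "volume", "n_blebs",
            "max_bleb_diameter", "Lmax_over_Dinit")
  missing <- setdiff(cols, names(samples))
  if (length(missing)) stop("time series lacks columns: ",
                            paste(missing, collapse = ", "))
  df <- as.data.frame(samples)[, cols]
  for (cn in cols) {
    if (is.numeric(df[[cn]]) && cn != "n_blebs") df[[cn]] <- fmt17(df[[cn]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Load simulation parameters from a YAML or key:value config file
#'
#' Recognizes all [sim_params()] fields plus `region`; unknown keys are an
#' error.
#'
#' @param path Config file path.
#' @return A `sim_params` with a `region` attribute if given.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  region <- cfg$region
  cfg$region <- NULL
  p <- do.call(sim_params, cfg)
  if (!is.null(region)) attr(p, "region") <- region
  p
}

#' Run manifest
#'
#' Full parameter echo plus seed and format versions: sufficient to
#' reproduce a run exactly.
#'
#' @param params A `sim_params`.
#' @param seed Integer seed (drawn and recorded when `NULL`).
#' @param path Optional output JSON path.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(params, seed = NULL, path = NULL) {
  if (is.null(seed)) seed <- params$seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  man <- list(
    tool = "cortosim",
    version = as.character(utils::packageVersion("cortosim")),
    format_version = 1L,
    seed = as.integer(seed),
    region = attr(params, "region"),
    params = unclass(params))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, digits = NA, auto_unbox = TRUE, na = "null")
    return(invisible(man))
  }
  man
}

#' Per-run analysis summary
#'
#' One-row tibble summarising a trajectory: morphology class, distinct bleb
#' count, initiation mechanisms, deformation magnitude and final tensions.
#'
#' @param traj A `cortosim_trajectory`.
#' @return A tibble with one row.
#' @export
summarize_run <- function(traj) {
  tracks <- track_blebs(traj)
  mech <- if (length(tracks)) {
    vapply(tracks, function(tr) {
      tryCatch(classify_initiation(traj, tr), error = function(e) "Undetermined")
    }, "")
  } else character(0)
  last <- traj$series[nrow(traj$series), ]
  tibble::tibble(
    seed = traj$seed, region = traj$region,
    morphology = classify_morphology(traj),
    n_blebs = length(tracks),
    mechanisms = paste(mech, collapse = ";"),
    Lmax_over_Dinit = deformation_magnitude(traj),
    max_bleb_diameter = if (length(tracks)) max(vapply(tracks, `[[`, 0, "max_diameter")) else 0,
    n_sever_events = sum(traj$events$type == "sever"),
    T_net_final = last$T_net_global, T_mem_final = last$T_mem_global)
}
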