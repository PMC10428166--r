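#' Read and write photon record tables
#'
#' The on-disk photon format is a plain CSV with columns `channel`
#' (`donor`/`acceptor`), `macro_time_s` and `micro_time_ns`. Reading
#' validates the table (unknown channels and malformed numbers are
#' reported with their line numbers; unsorted macro times are rejected);
#' the round trip is lossless to the printed precision.
#'
#' @param file path to a CSV file.
#' @param micro_period excitation period (ns) to validate micro times
#'   against.
#' @return `read_photons()`: a [photon_records()] table.
#' @export
read_photons <- function(file, micro_period = 50) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("channel", "macro_time_s", "micro_time_ns")
  if (!all(need %in% names(df)))
    stop("photon file must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  bad <- which(!df$channel %in% c("donor", "acceptor") |
                 !is.finite(suppressWarnings(as.numeric(df$macro_time_s))) |
                 !is.finite(suppressWarnings(as.numeric(df$micro_time_ns))))
  if (length(bad))
    stop("malformed photon rows at line(s): ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "), call. = FALSE)
  photon_records(df$channel, as.numeric(df$macro_time_s),
                 as.numeric(df$micro_time_ns), micro_period = micro_period)
}

#' @rdname read_photons
#' @param photons a [photon_records()] table.
#' @export
write_photons <- function(photons, file) {
  if (!inherits(photons, "photon_records")) stop("`photons` must be photon_records", call. = FALSE)
  utils::write.csv(as.data.frame(photons), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper over `seqinr::read.fasta`: sequences are upper-cased and
#' validated against the 20 standard residue letters.
#'
#' @param file FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(file) {
  seqs <- seqinr::read.fasta(file, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  out <- toupper(vapply(seqs, as.character, character(1L)))
  ok <- names(residue_groups())
  for (nm in names(out)) {
    res <- strsplit(out[[nm]], "")[[1L]]
    if (!all(res %in% ok))
      stop("invalid residue letter(s) in '", nm, "': ",
           paste(unique(res[!res %in% ok]), collapse = ", "), call. = FALSE)
  }
  out
}

#' The 14 double-cysteine labeling variants
#'
#' Returns the alpha-synuclein sequence with the two label positions of
#' each construct substituted by cysteine (the attachment chemistry used
#' for maleimide dye labeling), named `"aS_<i>-<j>"`.
#'
#' @param constructs construct table (default [alphasyn_constructs()]).
#' @return named character vector of 140-residue sequences.
#' @export
alphasyn_variant_sequences <- function(constructs = alphasyn_constructs()) {
  wt <- strsplit(alphasyn_sequence(), "")[[1L]]
  out <- vapply(seq_len(nrow(constructs)), function(k) {
    v <- wt
    v[c(constructs$label_i[k], constructs$label_j[k])] <- "C"
    paste(v, collapse = "")
  }, character(1L))
  names(out) <- paste0("aS_", constructs$label_i, "-", constructs$label_j)
  out
}

#' Read and write XYZ trajectories
#'
#' Frame-per-block XYZ: a bead-count line, a comment line, then one
#' `element x y z` row per bead; coordinates in nm.
#'
#' @param ens a [sample_chain()] ensemble (or any `N x 3 x F` array in
#'   `write_xyz()`).
#' @param file path.
#' @export
write_xyz <- function(ens, file) {
  frames <- if (inherits(ens, "chain_ensemble")) ens$frames else ens
  d <- dim(frames)
  con <- file(file, "w"); on.exit(close(con))
  for (f in seq_len(d[3L])) {
    writeLines(c(as.character(d[1L]), sprintf("frame %d (nm)", f)), con)
    writeLines(sprintf("C %.6f %.6f %.6f", frames[, 1L, f], frames[, 2L, f],
                       frames[, 3L, f]), con)
  }
  invisible(file)
}

#' @rdname write_xyz
#' @return `read_xyz()`: an `N x 3 x F` array (nm).
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  if (!length(lines)) stop("empty XYZ file", call. = FALSE)
  N <- as.integer(lines[1L])
  block <- N + 2L
  if (length(lines) %% block != 0L) stop("malformed XYZ file", call. = FALSE)
  F <- length(lines) %/% block
  out <- array(NA_real_, c(N, 3L, F))
  for (f in seq_len(F)) {
    rows <- lines[((f - 1L) * block + 3L):((f - 1L) * block + 2L + N)]
    m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), function(p)
      as.numeric(p[2:4])))
    out[, , f] <- m
  }
  out
}

#' Write a multi-model PDB for visualization
#'
#' One MODEL per frame, one CA pseudo-atom per bead (coordinates
#' converted from nm to Angstrom). Minimal records only — intended for
#' molecular viewers, not for downstream parsing.
#'
#' @param ens a [sample_chain()] ensemble.
#' @param file path.
#' @param max_frames cap on frames written (default 100).
#' @export
write_ensemble_pdb <- function(ens, file, max_frames = 100L) {
  if (!inherits(ens, "chain_ensemble")) stop("`ens` must be a chain_ensemble", call. = FALSE)
  frames <- ens$frames
  d <- dim(frames)
  use <- seq_len(min(d[3L], max_frames))
  con <- file(file, "w"); on.exit(close(con))
  for (f in use) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                       seq_len(d[1L]), seq_len(d[1L]),
                       frames[, 1L, f] * 10, frames[, 2L, f] * 10,
                       frames[, 3L, f] * 10), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Run configuration
#'
#' All tunable constants of the pipeline in one validated record, with
#' defaults matching the analysis conventions used throughout the
#' package: 1 ms bins, 50/1000 photon thresholds, `E < 0.9` inclusion,
#' `gamma = 1.1615`, 0.38 nm bonds, 0.7 nm contact cutoff with
#' `|i - j| <= 3` exclusion, +4 dye-padding residues.
#'
#' @param ... overrides of the default fields.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(bin_ms = 1, min_photons = 50, max_photons = 1000, E_max = 0.9,
              gamma = saw_gamma(), b_bond = peptide_bond_length(),
              contact_cutoff = 0.7, contact_exclusion = 3L,
              dye_padding_residues = 4L, R0 = 6.2, tauD = 4.0,
              micro_period = 50, nu_range = c(0.3, 0.7), nu_step = 0.005,
              bg_donor = 0, bg_acceptor = 0, alpha_leak = 0, gamma_det = 1,
              irf_offset = 0, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  stopifnot(cfg$bin_ms > 0, cfg$min_photons >= 0,
            cfg$max_photons > cfg$min_photons,
            cfg$E_max > 0, cfg$E_max <= 1, cfg$R0 > 0)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param file YAML (`.yml`/`.yaml`) or JSON (`.json`) file of overrides.
#' @export
read_run_config <- function(file) {
  over <- if (grepl("\\.ya?ml$", file)) yaml::read_yaml(file)
          else jsonlite::fromJSON(file)
  do.call(run_config, over)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (nm in names(x))
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

cf_of_config <- function(cfg) {
  correction_factors(bg_donor = cfg$bg_donor, bg_acceptor = cfg$bg_acceptor,
                     alpha_leak = cfg$alpha_leak, gamma_det = cfg$gamma_det,
                     irf_offset = cfg$irf_offset)
}

#' Analysis report
#'
#' Collects the results of a run — the scaling fit, per-construct table,
#' deviation map data, configuration echo and seeds — into a report that
#' prints as a human-readable summary and serializes to JSON
#' deterministically. Stages that were not run are flagged and the
#' report marked partial.
#'
#' @param fit a [flory_fit()] (or `NULL` if the stage was not run).
#' @param config a [run_config()] echo.
#' @param seeds named integer vector of seeds used.
#' @param file optional path to also write the JSON to.
#' @return object of class `"sawfret_report"` (a list), invisibly if
#'   `file` is given.
#' @export
sawfret_report <- function(fit = NULL, config = run_config(), seeds = NULL,
                           file = NULL) {
  rep <- list(
    partial = is.null(fit),
    missing_stages = if (is.null(fit)) "scaling_fit" else character(0),
    nu_star = if (!is.null(fit)) fit$nu_star,
    lp = if (!is.null(fit)) fit$lp,
    constructs = if (!is.null(fit)) fit$observations,
    deviation_points = if (!is.null(fit) && !is.null(fit$devmap)) fit$devmap$points,
    config = unclass(config), seeds = seeds)
  class(rep) <- "sawfret_report"
  if (!is.null(file)) {
    jsonlite::write_json(unclass(rep), file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    return(invisible(rep))
  }
  rep
}

#' @export
print.sawfret_report <- function(x, ...) {
  cat("smFRET polymer-scaling report",
      if (x$partial) "(PARTIAL: missing stages:" else "",
      if (x$partial) paste(x$missing_stages, collapse = ", "), if (x$partial) ")",
      "\n")
  if (!is.null(x$nu_star))
    cat(sprintf("  nu* = %.3f; lp = %.3f nm\n", x$nu_star, x$lp))
  if (!is.null(x$constructs)) {
    cat(sprintf("  %d constructs (%d included)\n", nrow(x$constructs),
                sum(x$constructs$included)))
  }
  cat(sprintf("  seeds: %s\n",
              if (is.null(x$seeds)) "(none recorded)"
              else paste(names(x$seeds), x$seeds, sep = "=", collapse = ", ")))
  invisible(x)
}
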