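#' Wild-type alpha-synuclein sequence and residue grouping
#'
#' `alphasyn_sequence()` returns the 140-residue human alpha-synuclein
#' sequence. `residue_groups()` returns the five-way partition of the 20
#' amino acids used for grouped contact maps: cationic (R, K), anionic
#' (D, E), aromatic (F, Y, W), hydrophobic aliphatic (A, C, I, L, M, P,
#' V) and hydrophilic (G, N, S, H, Q, T).
#'
#' @return `alphasyn_sequence()`: a single string;
#'   `residue_groups()`: named character vector mapping residue letters to
#'   group names.
#' @export
alphasyn_sequence <- function() {
  paste0("MDVFMKGLSKAKEGVVAAAEKTKQGVAEAAGKTKEGVLYV",
         "GSKTKEGVVHGVATVAEKTKEQVTNVGGAVVTGVTAVAQK",
         "TVEGAGSIAAATGFVKKDQLGKNEEGAPQEGILEDMPVDP",
         "DNEAYEMPSEEGYQDYEPEA")
}

#' @rdname alphasyn_sequence
#' @export
residue_groups <- function() {
  c(R = "cationic", K = "cationic",
    D = "anionic", E = "anionic",
    F = "aromatic", Y = "aromatic", W = "aromatic",
    A = "aliphatic", C = "aliphatic", I = "aliphatic", L = "aliphatic",
    M = "aliphatic", P = "aliphatic", V = "aliphatic",
    G = "hydrophilic", N = "hydrophilic", S = "hydrophilic",
    H = "hydrophilic", Q = "hydrophilic", T = "hydrophilic")
}

group_levels <- function() c("cationic", "anionic", "aromatic", "aliphatic", "hydrophilic")

## per-residue formal charges at pH 7.4 (D/E -1, K/R +1, H neutral)
residue_charges <- function(residues, termini_charged = TRUE) {
  q <- rep(0, length(residues))
  q[residues %in% c("K", "R")] <- 1
  q[residues %in% c("D", "E")] <- -1
  if (termini_charged && length(residues)) {
    q[1L] <- q[1L] + 1          # N-terminal amine
    q[length(residues)] <- q[length(residues)] - 1  # C-terminal carboxyl
  }
  q
}

default_attraction <- function() {
  g <- group_levels()
  eps <- matrix(0, 5, 5, dimnames = list(g, g))
  eps["aliphatic", "aliphatic"] <- 0.30
  eps["aliphatic", "aromatic"] <- eps["aromatic", "aliphatic"] <- 0.30
  eps["aromatic", "aromatic"] <- 0.35
  eps["cationic", "aromatic"] <- eps["aromatic", "cationic"] <- 0.50  # cation-pi
  eps
}

#' Coarse-grained one-bead-per-residue chain model
#'
#' A deliberately simple stand-in for residue-resolved coarse-grained
#' force fields: beads on a fixed 0.38 nm bond, a hard-core excluded
#' volume, a per-residue bending stiffness (enhanced at prolines), Debye
#' screened electrostatics from the formal charges at pH 7.4, and a
#' square-well attraction between residue groups whose cation-pi cell
#' couples K/R to F/Y/W. Well depths are qualitative defaults in kT; the
#' sampler targets equilibrium ensemble averages, not dynamics.
#'
#' @param sequence amino-acid string (default the alpha-synuclein
#'   sequence).
#' @param b_bond bond length (nm).
#' @param bead_diameter hard-core diameter (nm); 0 disables excluded
#'   volume (ideal chain).
#' @param k_bend base bending stiffness per interior residue (kT).
#' @param k_bend_proline stiffness at proline positions (kT).
#' @param debye_length Debye screening length (nm); about 0.78 nm at
#'   physiological (1x PBS) ionic strength.
#' @param bjerrum_length Bjerrum length (nm), 0.7 in water at room
#'   temperature.
#' @param attraction 5x5 symmetric matrix of square-well depths (kT) by
#'   residue group; `NULL` for the defaults, `0` to disable.
#' @param well_cutoff attraction range (nm).
#' @param termini_charged add +1/-1 at the chain termini.
#' @return object of class `"chain_model"`.
#' @export
chain_model <- function(sequence = alphasyn_sequence(),
                        b_bond = peptide_bond_length(),
                        bead_diameter = 0.38,
                        k_bend = 0.5, k_bend_proline = 3,
                        debye_length = 0.78, bjerrum_length = 0.7,
                        attraction = NULL, well_cutoff = 0.7,
                        termini_charged = TRUE) {
  res <- strsplit(toupper(sequence), "")[[1L]]
  groups <- residue_groups()
  if (!all(res %in% names(groups)))
    stop("unknown residue letter(s): ",
         paste(unique(res[!res %in% names(groups)]), collapse = ", "), call. = FALSE)
  if (debye_length <= 0) stop("`debye_length` must be positive", call. = FALSE)
  if (is.null(attraction)) attraction <- default_attraction()
  if (identical(attraction, 0)) attraction <- matrix(0, 5, 5,
    dimnames = list(group_levels(), group_levels()))
  if (!isTRUE(all.equal(attraction, t(attraction))))
    stop("`attraction` must be symmetric", call. = FALSE)
  kb <- rep(k_bend, length(res))
  kb[res == "P"] <- k_bend_proline
  structure(list(sequence = paste(res, collapse = ""), residues = res,
                 n_residues = length(res), b_bond = b_bond,
                 bead_diameter = bead_diameter, k_bend = kb,
                 charges = residue_charges(res, termini_charged),
                 debye_length = debye_length, bjerrum_length = bjerrum_length,
                 attraction = attraction, well_cutoff = well_cutoff,
                 group_index = match(unname(groups[res]), group_levels()) - 1L),
            class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf("Coarse-grained chain: %d residues, b = %.2f nm, hard core %.2f nm\n",
              x$n_residues, x$b_bond, x$bead_diameter))
  cat(sprintf("  bend %.2g kT (proline %.2g), Debye length %.2f nm, net charge %+d\n",
              min(x$k_bend), max(x$k_bend), x$debye_length, sum(x$charges)))
  invisible(x)
}

#' Sample chain conformations by Metropolis Monte Carlo
#'
#' Pivot and crankshaft moves on the fixed-bond chain; the observables of
#' interest (label-pair distances, contact fractions, shape metrics) are
#' equilibrium averages, which Monte Carlo reaches directly without
#' simulating dynamics. Frames are stored every `stride` attempted moves
#' after a `burnin` equilibration discard; the same seed reproduces the
#' trajectory exactly.
#'
#' @param model a [chain_model()].
#' @param n_frames number of frames to store.
#' @param seed integer seed (applied via `set.seed()`).
#' @param stride attempted moves between stored frames (default `2 N`).
#' @param burnin equilibration moves discarded up front (default `200 N`).
#' @return object of class `"chain_ensemble"`: `frames` (an
#'   `N x 3 x n_frames` array, nm, centred per frame), the model, and the
#'   sampler acceptance rate.
#' @export
sample_chain <- function(model, n_frames, seed = 1L, stride = NULL,
                         burnin = NULL) {
  if (!inherits(model, "chain_model")) stop("`model` must be a chain_model", call. = FALSE)
  N <- model$n_residues
  if (is.null(stride)) stride <- 2L * N
  if (is.null(burnin)) burnin <- 200L * N
  set.seed(seed)
  out <- .sample_chain_cpp(N, as.integer(n_frames), as.integer(stride),
                           as.integer(burnin), model$b_bond,
                           model$bead_diameter, model$k_bend, model$charges,
                           model$bjerrum_length, model$debye_length,
                           model$attraction, model$group_index,
                           model$well_cutoff)
  if (out$acceptance < 0.01)
    warning(sprintf("Monte Carlo acceptance rate %.2f%% is very low",
                    100 * out$acceptance), call. = FALSE)
  structure(list(frames = out$frames, model = model, seed = seed,
                 stride = stride, burnin = burnin,
                 acceptance = out$acceptance),
            class = "chain_ensemble")
}

#' @export
print.chain_ensemble <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Chain ensemble: %d beads x %d frames (seed %d, acceptance %.1f%%)\n",
              d[1L], d[3L], x$seed, 100 * x$acceptance))
  invisible(x)
}

#' Mean distance between two labeled residues
#'
#' Frame-averaged Euclidean distance between beads `i` and `j`. With
#' `dye_mode = "bead_offset"` the combined dye-linker correction
#' (`0.76 * 2^(3/5) = 1.15` nm, see [dye_linker_offset()]) is added, so
#' the value is comparable to FRET-derived dye-to-dye distances.
#'
#' @param ens a [sample_chain()] ensemble.
#' @param i,j 1-based bead indices, `i != j`.
#' @param dye_mode `"none"` or `"bead_offset"`.
#' @return mean distance in nm.
#' @export
label_distance <- function(ens, i, j, dye_mode = c("none", "bead_offset")) {
  dye_mode <- match.arg(dye_mode)
  if (!inherits(ens, "chain_ensemble")) stop("`ens` must be a chain_ensemble", call. = FALSE)
  N <- dim(ens$frames)[1L]
  if (i == j) stop("`i` and `j` must differ", call. = FALSE)
  if (min(i, j) < 1L || max(i, j) > N) stop("bead index out of range", call. = FALSE)
  d <- sqrt(colSums((ens$frames[i, , ] - ens$frames[j, , ])^2))
  mean(d) + if (dye_mode == "bead_offset") dye_linker_offset() else 0
}

#' Time-averaged residue contact map
#'
#' Fraction of frames in which each residue pair lies within `cutoff`
#' (bead centres); pairs within `exclusion` positions along the chain are
#' excluded (their proximity is a trivial consequence of connectivity).
#' `n_contact` gives the average number of contacts each residue has at
#' any given time (row sums of the fraction matrix).
#'
#' @param ens a [sample_chain()] ensemble.
#' @param cutoff contact distance (nm), default 0.7.
#' @param exclusion band half-width: pairs with `|i - j| <= exclusion`
#'   are ignored (default 3).
#' @return object of class `"contact_map"`: `fractions` (symmetric
#'   `N x N`), `n_contact`, `cutoff`, `exclusion`, `n_frames`.
#' @export
contact_map <- function(ens, cutoff = 0.7, exclusion = 3L) {
  if (!inherits(ens, "chain_ensemble")) stop("`ens` must be a chain_ensemble", call. = FALSE)
  fr <- .contact_map_cpp(ens$frames, cutoff, as.integer(exclusion))
  structure(list(fractions = fr, n_contact = rowSums(fr),
                 cutoff = cutoff, exclusion = as.integer(exclusion),
                 n_frames = dim(ens$frames)[3L],
                 sequence = ens$model$sequence),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("Contact map: %d residues, cutoff %.2f nm, |i-j| <= %d excluded, %d frames\n",
              nrow(x$fractions), x$cutoff, x$exclusion, x$n_frames))
  cat(sprintf("  mean contacts per residue: %.3f\n", mean(x$n_contact)))
  invisible(x)
}

#' Contact map grouped by residue class, abundance-normalized
#'
#' Aggregates the residue-level contact fractions into the five residue
#' groups and divides each cell by the number of available residue pairs
#' of that group combination (pairs inside the exclusion band are not
#' available), so group abundance does not masquerade as interaction
#' preference.
#'
#' @param cm a [contact_map()].
#' @param sequence amino-acid string matching the map (defaults to the
#'   sequence recorded in the map).
#' @return 5x5 symmetric matrix of mean per-pair contact fractions.
#' @export
grouped_contact_map <- function(cm, sequence = cm$sequence) {
  if (!inherits(cm, "contact_map")) stop("`cm` must be a contact_map", call. = FALSE)
  res <- strsplit(toupper(sequence), "")[[1L]]
  if (length(res) != nrow(cm$fractions))
    stop("sequence length does not match the contact map", call. = FALSE)
  groups <- residue_groups()
  if (!all(res %in% names(groups)))
    stop("unknown residue letter(s) in `sequence`", call. = FALSE)
  gi <- factor(unname(groups[res]), levels = group_levels())
  N <- length(res)
  avail <- outer(seq_len(N), seq_len(N), function(i, j) abs(i - j) > cm$exclusion)
  g <- group_levels()
  out <- matrix(0, 5, 5, dimnames = list(g, g))
  for (ga in seq_len(5L)) for (gb in ga:5L) {
    ia <- which(as.integer(gi) == ga); ib <- which(as.integer(gi) == gb)
    if (!length(ia) || !length(ib)) next
    sel <- avail[ia, ib, drop = FALSE]
    n_pairs <- sum(sel)
    if (n_pairs == 0) next
    out[ga, gb] <- out[gb, ga] <- sum(cm$fractions[ia, ib, drop = FALSE][sel]) / n_pairs
  }
  out
}

#' Gyration-tensor shape metrics of an ensemble
#'
#' Per frame, the gyration tensor `S = mean over beads of dr dr^T` is
#' diagonalized (eigenvalues `l1 >= l2 >= l3`). Reported metrics, using
#' `tr = l1 + l2 + l3` and `lbar = tr / 3`:
#'
#' * radius of gyration `Rg = sqrt(tr)`;
#' * normalized asphericity `Delta = 3/2 * sum((li - lbar)^2) / tr^2`,
#'   0 for a sphere, 1 for a rod;
#' * shape parameter `S = 27 * prod(li - lbar) / tr^3`, in
#'   `[-1/4, 2]`: negative for oblate, positive for prolate shapes
#'   (2 for a rod).
#'
#' @param ens a [sample_chain()] ensemble.
#' @return list with `Rg`, `asphericity`, `shape` (each `c(mean, sd)`) and
#'   the per-frame table; degenerate frames (zero extent) are dropped with
#'   a warning.
#' @export
shape_metrics <- function(ens) {
  if (!inherits(ens, "chain_ensemble")) stop("`ens` must be a chain_ensemble", call. = FALSE)
  F <- dim(ens$frames)[3L]
  per <- t(vapply(seq_len(F), function(f) {
    xyz <- ens$frames[, , f]
    xyz <- sweep(xyz, 2L, colMeans(xyz))
    ev <- sort(eigen(crossprod(xyz) / nrow(xyz), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    tr <- sum(ev)
    if (tr < 1e-12) return(c(NA_real_, NA_real_, NA_real_))
    lbar <- tr / 3
    c(Rg = sqrt(tr),
      asphericity = 1.5 * sum((ev - lbar)^2) / tr^2,
      shape = 27 * prod(ev - lbar) / tr^3)
  }, numeric(3L)))
  colnames(per) <- c("Rg", "asphericity", "shape")
  if (anyNA(per)) {
    warning(sum(!stats::complete.cases(per)), " degenerate frame(s) dropped", call. = FALSE)
    per <- per[stats::complete.cases(per), , drop = FALSE]
  }
  list(Rg = c(mean = mean(per[, "Rg"]), sd = stats::sd(per[, "Rg"])),
       asphericity = c(mean = mean(per[, "asphericity"]), sd = stats::sd(per[, "asphericity"])),
       shape = c(mean = mean(per[, "shape"]), sd = stats::sd(per[, "shape"])),
       per_frame = as.data.frame(per))
}
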