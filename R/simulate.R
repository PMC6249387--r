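#' Configuration for a synthetic scID-seq experiment
#'
#' Defines the plate design, panel composition, count model and read model
#' of a simulated experiment. Defaults emulate the reference design: a
#' 96-well-plate run with 84 single-cell wells and 48 empty background
#' wells, a 69-antibody panel (34 phospho epitopes, 11 of them paired with
#' their total protein), ~1% technical background, a mean PCR duplication
#' of 2 extra reads per molecule, and a latent differentiation trajectory
#' driving six anchor markers (ITGB1, ITGA6, TP63 down; NICD, KLF4, TGM1
#' up) along logistic curves with staggered midpoints.
#'
#' Per-cell counts are negative-binomial around trajectory-modulated means
#' (overdispersion is the norm in molecular count data; `dispersion = Inf`
#' recovers Poisson), empty wells are Poisson background, and per-cell
#' depth varies log-normally around `mean_depth`.
#'
#' @param n_cell_wells,n_empty_wells Plate design (defaults 84 / 48).
#' @param panel_size Number of antibody-DNA conjugates (default 69; at
#'   least 6, the trajectory markers).
#' @param mean_depth Expected UMI total per cell well (default 3000).
#' @param background_fraction Expected empty-well total as a fraction of
#'   the cell expectation (default 0.01).
#' @param duplication_rate Mean extra PCR reads per molecule; each
#'   molecule is sequenced `1 + Poisson(duplication_rate)` times.
#' @param error_rate Per-base substitution probability in reads.
#' @param dispersion Negative-binomial size parameter (default 10;
#'   `Inf` = Poisson).
#' @param noise_sd Log-normal sd of the per-cell depth factor.
#' @param marker_fold Fold-change of each marker between trajectory ends.
#' @param marker_steepness Logistic steepness of the marker curves.
#' @param marker_midpoints Logistic midpoints for the six markers
#'   (staggered, giving distinct kinetics).
#' @param marker_abundance Abundance weight of markers relative to the
#'   median antibody (markers are well-detected proteins).
#' @param frac_dynamic Fraction of non-marker antibodies given a mild
#'   (2-fold) random dynamic profile; the rest are static.
#' @param gate_cut Latent-time cut assigning FACS gates: cells with latent
#'   time below it are `ITGB1+`, the rest `ITGB1low` (default 0.7, a
#'   roughly 3:1 split).
#' @param well_bc_len Well-barcode length (default 8 nt).
#' @param min_barcode_distance Minimum pairwise Hamming distance enforced
#'   when drawing barcodes (default 3, supporting 1-mismatch correction).
#' @param seed Master seed; all simulator randomness derives from it.
#' @return A validated `scid_sim_config` list.
#' @export
sim_config <- function(n_cell_wells = 84L, n_empty_wells = 48L,
                       panel_size = 69L, mean_depth = 3000,
                       background_fraction = 0.01, duplication_rate = 2,
                       error_rate = 0.001, dispersion = 10,
                       noise_sd = 0.15, marker_fold = 6,
                       marker_steepness = 8,
                       marker_midpoints = c(0.45, 0.35, 0.55, 0.50, 0.60, 0.65),
                       marker_abundance = 7, frac_dynamic = 0.3,
                       gate_cut = 0.7, well_bc_len = 8L,
                       min_barcode_distance = 3L, seed = 1L) {
  cfg <- list(
    n_cell_wells = as.integer(n_cell_wells),
    n_empty_wells = as.integer(n_empty_wells),
    panel_size = as.integer(panel_size),
    mean_depth = mean_depth,
    background_fraction = background_fraction,
    duplication_rate = duplication_rate,
    error_rate = error_rate,
    dispersion = dispersion,
    noise_sd = noise_sd,
    marker_fold = marker_fold,
    marker_steepness = marker_steepness,
    marker_midpoints = marker_midpoints,
    marker_abundance = marker_abundance,
    frac_dynamic = frac_dynamic,
    gate_cut = gate_cut,
    well_bc_len = as.integer(well_bc_len),
    min_barcode_distance = as.integer(min_barcode_distance),
    seed = as.integer(seed)
  )
  if (cfg$n_cell_wells < 1L) stop("n_cell_wells must be positive")
  if (cfg$n_empty_wells < 0L) stop("n_empty_wells must be non-negative")
  if (cfg$panel_size < 6L) {
    stop("panel_size must be at least 6 (the trajectory markers)")
  }
  if (cfg$mean_depth <= 0) stop("mean_depth must be positive")
  if (cfg$background_fraction < 0 || cfg$background_fraction >= 1) {
    stop("background_fraction must lie in [0, 1)")
  }
  if (cfg$error_rate < 0 || cfg$error_rate > 0.25) {
    stop("error_rate must lie in [0, 0.25]")
  }
  if (cfg$duplication_rate < 0) stop("duplication_rate must be non-negative")
  if (length(cfg$marker_midpoints) != 6L) {
    stop("marker_midpoints must have length 6")
  }
  structure(cfg, class = "scid_sim_config")
}

BASES <- c("A", "C", "G", "T")

random_nt <- function(n, len) {
  m <- matrix(sample.int(4L, n * len, replace = TRUE), nrow = n)
  do.call(paste0, lapply(seq_len(len), function(j) BASES[m[, j]]))
}

# greedy rejection sampling of n barcodes with pairwise (and vs `avoid`)
# Hamming distance >= min_dist; uses the current RNG state
generate_barcodes <- function(n, len, min_dist, avoid = character()) {
  split_chars <- function(x) {
    if (!length(x)) {
      matrix(character(), 0L, len)
    } else {
      do.call(rbind, strsplit(x, "", fixed = TRUE))
    }
  }
  kept <- character(0)
  kept_ch <- rbind(split_chars(avoid))
  attempts <- 0L
  while (length(kept) < n) {
    attempts <- attempts + 1L
    if (attempts > 2000L * n) {
      stop("could not generate ", n, " length-", len,
           " barcodes at min distance ", min_dist)
    }
    cand <- random_nt(1L, len)
    cch <- strsplit(cand, "", fixed = TRUE)[[1]]
    ok <- nrow(kept_ch) == 0L ||
      all(rowSums(kept_ch != matrix(cch, nrow(kept_ch), len,
                                    byrow = TRUE)) >= min_dist)
    if (ok) {
      kept <- c(kept, cand)
      kept_ch <- rbind(kept_ch, cch)
    }
  }
  kept
}

# panel composition: 6 trajectory markers, then phospho/total pairs, extra
# unpaired phospho epitopes (34 phospho in the full 69-tag design), and
# remaining total/other epitopes; pathway groups cycle over common pathways
build_sim_panel <- function(cfg) {
  p <- cfg$panel_size
  n_rest <- p - 6L
  n_paired <- min(11L, n_rest %/% 2L)
  n_xphospho <- max(0L, min(34L - n_paired, n_rest - 2L * n_paired))
  n_other <- n_rest - 2L * n_paired - n_xphospho

  name <- character(0); class_ <- character(0); partner <- character(0)
  pathway <- character(0)
  name <- SCID_MARKERS
  class_ <- c("receptor", "receptor", "total", "total", "total", "total")
  partner <- rep(NA_character_, 6L)
  pathway <- c("adhesion", "adhesion", "transcription", "Notch",
               "transcription", "differentiation")

  pathways_pool <- c("JAK-STAT", "WNT", "BMP", "EGF", "Notch",
                     "cell-cycle", "TGFb", "other")
  k <- 0L
  for (i in seq_len(n_paired)) {
    k <- k + 1L
    pg <- pathways_pool[(i - 1L) %% length(pathways_pool) + 1L]
    tot <- sprintf("PROT%02d", k)
    name <- c(name, paste0("p", tot), tot)
    class_ <- c(class_, "phospho", "total")
    partner <- c(partner, tot, NA_character_)
    pathway <- c(pathway, pg, pg)
  }
  for (i in seq_len(n_xphospho)) {
    k <- k + 1L
    name <- c(name, sprintf("pPROT%02d", k))
    class_ <- c(class_, "phospho")
    partner <- c(partner, NA_character_)
    pathway <- c(pathway,
                 pathways_pool[(n_paired + i - 1L) %% length(pathways_pool) + 1L])
  }
  for (i in seq_len(n_other)) {
    k <- k + 1L
    name <- c(name, sprintf("PROT%02d", k))
    class_ <- c(class_, "total")
    partner <- c(partner, NA_character_)
    pathway <- c(pathway, "other")
  }

  tags <- data.frame(
    antibody_name = name,
    barcode = generate_barcodes(p, 10L, cfg$min_barcode_distance),
    epitope_class = class_,
    total_partner = partner,
    pathway_group = pathway,
    replicate_group = NA_character_,
    stringsAsFactors = FALSE
  )
  scid_panel(tags)
}

build_sim_plate <- function(cfg) {
  n <- cfg$n_cell_wells + cfg$n_empty_wells
  scid_plate(data.frame(
    well_barcode = generate_barcodes(n, cfg$well_bc_len,
                                     cfg$min_barcode_distance),
    well_id = sprintf("W%03d", seq_len(n)),
    well_type = rep(c("cell", "empty"), c(cfg$n_cell_wells, cfg$n_empty_wells)),
    gate_label = "none",
    stringsAsFactors = FALSE
  ))
}

logistic <- function(t, midpoint, steepness) {
  1 / (1 + exp(-steepness * (t - midpoint)))
}

#' Simulate ground-truth molecule counts along a differentiation trajectory
#'
#' Draws a full synthetic experiment: a plate (cell + empty wells with
#' distance-separated well barcodes), a panel (distance-separated antibody
#' barcodes), per-cell latent differentiation times (uniform on \[0, 1\]),
#' and a wells x antibodies matrix of true molecule counts. Marker means
#' follow logistic curves in their configured direction, a fraction of
#' non-marker antibodies get mild random dynamics, per-cell depth varies
#' log-normally, counts are negative-binomial, and empty wells carry
#' Poisson background scaled to `background_fraction`. FACS gate labels
#' derive from latent time via `gate_cut`. Fully deterministic under the
#' config seed.
#'
#' @param config A `scid_sim_config` from [sim_config()].
#' @return A `scid_sim`: list with `latent_time` (per cell),
#'   `true_counts` (wells x antibodies integer matrix, cell wells first),
#'   `gate_label` (per cell), `plate`, `panel`, `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "scid_sim_config"))
  withr::with_seed(config$seed, {
    panel <- build_sim_panel(config)
    plate <- build_sim_plate(config)
    n <- config$n_cell_wells
    p <- config$panel_size

    latent_time <- runif(n)
    gate_label <- ifelse(latent_time < config$gate_cut, "ITGB1+", "ITGB1low")
    plate$gate_label[plate$well_type == "cell"] <- gate_label

    # static abundance weights; markers boosted to well-detected levels
    w <- rlnorm(p, meanlog = 0, sdlog = 1)
    w[1:6] <- config$marker_abundance

    # trajectory profiles in (0, 1]; markers: logistic between 1/fold and 1
    f <- matrix(1, n, p)
    dir6 <- unname(SCID_MARKER_DIRECTION[SCID_MARKERS])
    for (j in 1:6) {
      lg <- logistic(latent_time, config$marker_midpoints[j],
                     config$marker_steepness)
      if (dir6[j] < 0) lg <- 1 - lg
      f[, j] <- (1 + (config$marker_fold - 1) * lg) / config$marker_fold
    }
    nonmarkers <- setdiff(seq_len(p), 1:6)
    n_dyn <- round(config$frac_dynamic * length(nonmarkers))
    if (n_dyn > 0) {
      dyn <- sample(nonmarkers, n_dyn)
      for (j in dyn) {
        lg <- logistic(latent_time, runif(1, 0.2, 0.8), 6)
        if (runif(1) < 0.5) lg <- 1 - lg
        f[, j] <- (1 + lg) / 2
      }
    }

    mu <- sweep(f, 2L, w, "*")
    size_factor <- rlnorm(n, meanlog = -config$noise_sd^2 / 2,
                          sdlog = config$noise_sd)
    mu <- mu / rowSums(mu) * config$mean_depth * size_factor

    cell_counts <- if (is.finite(config$dispersion)) {
      matrix(rnbinom(n * p, size = config$dispersion, mu = mu), n, p)
    } else {
      matrix(rpois(n * p, lambda = mu), n, p)
    }

    # empty wells: Poisson background, expected total = bf * mean_depth
    empty_mu <- config$background_fraction * config$mean_depth * w / sum(w)
    empty_counts <- matrix(
      rpois(config$n_empty_wells * p, lambda = rep(empty_mu,
                                                   each = config$n_empty_wells)),
      config$n_empty_wells, p
    )

    true_counts <- rbind(cell_counts, empty_counts)
    storage.mode(true_counts) <- "integer"
    rownames(true_counts) <- plate$well_id
    colnames(true_counts) <- panel$tags$antibody_name

    structure(list(
      latent_time = latent_time,
      true_counts = true_counts,
      gate_label = gate_label,
      plate = plate,
      panel = panel,
      config = config
    ), class = "scid_sim")
  })
}

#' @export
print.scid_sim <- function(x, ...) {
  cat(sprintf("scid_sim: %d cell + %d empty wells, %d antibodies, %d molecules\n",
              x$config$n_cell_wells, x$config$n_empty_wells,
              x$config$panel_size, sum(x$true_counts)))
  invisible(x)
}

#' True counts as a raw count matrix
#'
#' Packages the simulator's true molecule matrix as a `scid_counts` in
#' state `raw`, i.e. what a perfect (error-free, duplicate-collapsed)
#' pipeline would recover.
#'
#' @param truth A `scid_sim`.
#' @return A `scid_counts`.
#' @export
sim_counts <- function(truth) {
  stopifnot(inherits(truth, "scid_sim"))
  scid_counts(truth$true_counts,
              as.data.frame(truth$plate)[, c("well_id", "well_type",
                                             "gate_label")],
              truth$panel$tags, state = "raw")
}

#' Simulate sequencing reads from ground-truth molecules
#'
#' Emits the read set a sequencer would produce from the true molecules:
#' each molecule receives a distinct random 15-nt UMI (distinct within its
#' (well, antibody) group), is amplified into `1 + Poisson(duplication_rate)`
#' reads, per-base substitutions are applied at `error_rate`, and the reads
#' are shuffled. Optionally injects exactly one substitution into the
#' antibody-barcode segment of every read (`inject_ab_errors = TRUE`) to
#' exercise error correction.
#'
#' @param truth A `scid_sim`.
#' @param layout A `scid_layout`; default places well barcode, antibody
#'   barcode and UMI in-line in that order.
#' @param out_fastq Optional path (plain or `.gz`) to write a FASTQ file.
#' @param inject_ab_errors Force exactly one substitution at a random
#'   position of the antibody-barcode segment of every read; `error_rate`
#'   is ignored while this flag is set, so the injected error is each
#'   read's only one.
#' @param seed Seed for the read-level randomness (default: config seed
#'   + 1, so truth and reads are jointly reproducible).
#' @return List with `reads` (character vector of read sequences, shuffled),
#'   `molecules` (data.table: `well_id`, `antibody_name`, `umi`, one row
#'   per true molecule), `layout`, and `fastq` (path or `NULL`).
#' @export
simulate_reads <- function(truth, layout = NULL, out_fastq = NULL,
                           inject_ab_errors = FALSE, seed = NULL) {
  stopifnot(inherits(truth, "scid_sim"))
  cfg <- truth$config
  if (is.null(layout)) {
    layout <- read_layout(well_bc = c(0L, cfg$well_bc_len),
                          ab_bc = c(cfg$well_bc_len, 10L),
                          umi = c(cfg$well_bc_len + 10L, 15L))
  }
  if ((cfg$error_rate > 0 || inject_ab_errors) &&
      truth$panel$min_pairwise_distance < 3L) {
    stop("error injection requires panel barcodes at pairwise Hamming ",
         "distance >= 3")
  }
  if (is.null(seed)) seed <- cfg$seed + 1L

  withr::with_seed(as.integer(seed), {
    counts <- truth$true_counts
    nz <- which(counts > 0L, arr.ind = TRUE)
    well_idx <- rep.int(nz[, 1L], counts[nz])
    ab_idx <- rep.int(nz[, 2L], counts[nz])
    n_mol <- length(well_idx)

    umi <- random_nt(n_mol, 15L)
    umi <- make_umis_distinct(umi, well_idx, ab_idx)

    molecules <- data.table(
      well_id = truth$plate$well_id[well_idx],
      antibody_name = truth$panel$tags$antibody_name[ab_idx],
      umi = umi
    )

    copies <- 1L + rpois(n_mol, cfg$duplication_rate)
    ri <- rep.int(seq_len(n_mol), copies)
    reads <- paste0(truth$plate$well_barcode[well_idx][ri],
                    truth$panel$tags$barcode[ab_idx][ri],
                    umi[ri])
    n_reads <- length(reads)

    if (inject_ab_errors) {
      pos <- layout$ab_bc[1] + sample.int(10L, n_reads, replace = TRUE)
      reads <- substitute_base(reads, pos)
    } else if (cfg$error_rate > 0) {
      read_len <- nchar(reads[1])
      n_err <- stats::rbinom(n_reads, read_len, cfg$error_rate)
      r <- 1L
      while (any(n_err >= r)) {
        sel <- which(n_err >= r)
        pos <- sample.int(read_len, length(sel), replace = TRUE)
        reads[sel] <- substitute_base(reads[sel], pos)
        r <- r + 1L
      }
    }

    reads <- reads[sample.int(n_reads)]

    fastq <- NULL
    if (!is.null(out_fastq)) {
      write_fastq(reads, out_fastq)
      fastq <- out_fastq
    }
    list(reads = reads, molecules = molecules, layout = layout,
         fastq = fastq)
  })
}

# replace the base at `pos` in each read with a different random base
substitute_base <- function(reads, pos) {
  old <- substr(reads, pos, pos)
  shift <- sample.int(3L, length(reads), replace = TRUE)
  new <- BASES[(match(old, BASES) - 1L + shift) %% 4L + 1L]
  substr(reads, pos, pos) <- new
  reads
}

# regenerate duplicated UMIs until distinct within each (well, antibody)
make_umis_distinct <- function(umi, well_idx, ab_idx) {
  group <- paste(well_idx, ab_idx)
  repeat {
    dup <- duplicated(paste(group, umi))
    if (!any(dup)) break
    umi[dup] <- random_nt(sum(dup), 15L)
  }
  umi
}

write_fastq <- function(reads, path, qual_char = "I") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  n <- length(reads)
  quals <- strrep(qual_char, nchar(reads))
  writeLines(paste0("@read", seq_len(n), "\n", reads, "\n+\n", quals), con)
  invisible(path)
}

#' Simulate the replicate-barcode concordance design
#'
#' Emulates the technical-replicate experiment in which each of a handful
#' of antibodies is independently conjugated to several distinct DNA
#' barcodes (default: 5 antibodies x 9 barcodes = 45 conjugates). Each
#' selected antibody's true per-well molecule count is split multinomially
#' across its replicate barcodes with equal probabilities, so the replicate
#' columns sum exactly to the original column and their cross-cell
#' correlation measures assay reproducibility.
#'
#' @param truth A `scid_sim`.
#' @param n_replicates Barcodes per antibody (default 9).
#' @param antibodies Antibody names to replicate (default: the first 5
#'   panel entries).
#' @param seed Seed (default: config seed + 2).
#' @return List with `panel` (a `scid_panel` of the conjugates, with
#'   `replicate_group` = source antibody), `counts` (a raw `scid_counts`,
#'   wells x conjugates), `mapping` (data.frame `conjugate`, `antibody`).
#' @export
simulate_replicate_barcodes <- function(truth, n_replicates = 9L,
                                        antibodies = NULL, seed = NULL) {
  stopifnot(inherits(truth, "scid_sim"))
  cfg <- truth$config
  tags <- truth$panel$tags
  if (is.null(antibodies)) antibodies <- tags$antibody_name[1:5]
  missing_ab <- setdiff(antibodies, tags$antibody_name)
  if (length(missing_ab)) {
    stop("antibody not in panel: ", paste(missing_ab, collapse = ", "))
  }
  if (is.null(seed)) seed <- cfg$seed + 2L
  n_replicates <- as.integer(n_replicates)

  withr::with_seed(as.integer(seed), {
    n_conj <- length(antibodies) * n_replicates
    barcodes <- generate_barcodes(n_conj, 10L, cfg$min_barcode_distance,
                                  avoid = tags$barcode)
    n_wells <- nrow(truth$true_counts)
    vals <- matrix(0L, n_wells, n_conj)
    conj_names <- character(n_conj)
    group <- character(n_conj)
    k <- 0L
    for (ab in antibodies) {
      src <- truth$true_counts[, ab]
      cols <- k + seq_len(n_replicates)
      split_counts <- vapply(src, function(total) {
        rmultinom(1L, total, rep(1 / n_replicates, n_replicates))[, 1L]
      }, integer(n_replicates))
      vals[, cols] <- t(split_counts)
      conj_names[cols] <- sprintf("%s_bc%d", ab, seq_len(n_replicates))
      group[cols] <- ab
      k <- k + n_replicates
    }

    src_meta <- tags[match(group, tags$antibody_name), ]
    conj_tags <- data.frame(
      antibody_name = conj_names,
      barcode = barcodes,
      epitope_class = src_meta$epitope_class,
      total_partner = NA_character_,
      pathway_group = src_meta$pathway_group,
      replicate_group = group,
      stringsAsFactors = FALSE
    )
    panel <- scid_panel(conj_tags)
    counts <- scid_counts(
      vals,
      as.data.frame(truth$plate)[, c("well_id", "well_type", "gate_label")],
      panel$tags, state = "raw"
    )
    list(panel = panel, counts = counts,
         mapping = data.frame(conjugate = conj_names, antibody = group,
                              stringsAsFactors = FALSE))
  })
}
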