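#' Synthetic emission spectra over a temperature ramp
#'
#' Emulates intrinsic tryptophan fluorescence melts: at each temperature the
#' emission spectrum is a mixture of Gaussian components (folded, optional
#' intermediate, unfolded) whose mixing weights follow the same sigmoid
#' transition model the melt fits assume, so the analytic barycentric mean of
#' the noiseless spectrum equals the model melt curve. Component centres are
#' corrected for window truncation/discretisation so the discrete barycentric
#' mean matches the nominal centre to better than 0.01 nm. Intensity noise is
#' shot-noise-like Gaussian (sd proportional to sqrt(intensity)), calibrated
#' per spectrum so that the induced noise on the barycentric mean has
#' standard deviation `noise_sd` nanometres.
#'
#' @param tm1 First (or only) transition midpoint, degrees C.
#' @param a Cooperativity factor of the first transition, degrees C.
#' @param bcm_n,bcm_d Barycentric mean of the folded / unfolded state, nm
#'   (`bcm_d` must exceed `bcm_n`: unfolding red-shifts tryptophan emission).
#' @param tm2,b,bcm_2 Second transition parameters (all three, or none).
#' @param noise_sd Barycentric-mean-equivalent noise, nm.
#' @param temps Temperature ramp, degrees C (default 25..90 at 1 degree).
#' @param wavelengths Emission wavelength grid, nm.
#' @param width Gaussian component width (sd), nm.
#' @param seed Optional RNG seed for reproducibility.
#' @return A list with `spectra` (long data frame: `temperature`,
#'   `wavelength`, `intensity`) and `truth` (generating parameters plus the
#'   noiseless model barycentric mean per temperature).
#' @export
gen_melt_spectra <- function(tm1, a = 2, bcm_n = 352.2, bcm_d = 360,
                             tm2 = NULL, b = NULL, bcm_2 = NULL,
                             noise_sd = 0, temps = 25:90,
                             wavelengths = seq(280, 470, by = 1),
                             width = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (bcm_d <= bcm_n) {
    stop("bcm_d must exceed bcm_n: unfolding must red-shift the emission")
  }
  centers <- c(bcm_n, bcm_2, bcm_d)
  if (any(centers < 300) || any(centers > 450)) {
    stop("barycentric-mean parameters must lie within 300-450 nm")
  }
  two <- !is.null(tm2)
  if (two && (is.null(b) || is.null(bcm_2))) {
    stop("two-transition generation needs tm2, b and bcm_2")
  }
  total <- 1000
  # correct each component centre so its *discrete* barycentric mean on this
  # grid equals the nominal value (one fixed-point step suffices)
  discrete_bcm <- function(center) {
    i <- stats::dnorm(wavelengths, center, width)
    sum(wavelengths * i) / sum(i)
  }
  corrected <- vapply(centers, function(cc) 2 * cc - discrete_bcm(cc),
                      numeric(1))
  comp <- vapply(corrected, function(cc) {
    i <- stats::dnorm(wavelengths, cc, width)
    i / sum(i)
  }, numeric(length(wavelengths)))
  s1 <- 1 / (1 + exp((tm1 - temps) / a))
  if (two) {
    s2 <- 1 / (1 + exp((tm2 - temps) / b))
    w <- cbind(1 - s1, pmax(s1 - s2, 0), s2)
    model_bcm <- bcm_n + (bcm_2 - bcm_n) * s1 + (bcm_d - bcm_2) * s2
  } else {
    w <- cbind(1 - s1, s1)
    model_bcm <- bcm_n + (bcm_d - bcm_n) * s1
  }
  spectra <- do.call(rbind, lapply(seq_along(temps), function(k) {
    inten <- total * as.numeric(comp %*% w[k, ])
    if (noise_sd > 0) {
      bcm <- sum(wavelengths * inten) / sum(inten)
      scale2 <- sum((wavelengths - bcm)^2 * inten)
      s <- noise_sd * sum(inten) / sqrt(scale2)
      inten <- pmax(inten + stats::rnorm(length(inten), 0, s * sqrt(inten)), 0)
    }
    data.frame(temperature = temps[k], wavelength = wavelengths,
               intensity = inten)
  }))
  truth <- list(tm1 = tm1, a = a, bcm_n = bcm_n, bcm_d = bcm_d,
                red_shift = bcm_d - bcm_n, tm2 = tm2, b = b, bcm_2 = bcm_2,
                noise_sd = noise_sd, model_bcm = model_bcm,
                temperatures = temps)
  list(spectra = spectra, truth = truth)
}

#' Synthetic coupled-assay kinetic traces
#'
#' Emulates resorufin fluorescence traces from the coupled methyltransferase
#' assay: a linear rise that plateaus at `saturation_time`. The rate of a
#' variant with true activity ratio r is `ko_rate + r * (wt_rate - ko_rate)`;
#' replicate rates carry multiplicative Gaussian noise of coefficient of
#' variation `noise_cv`.
#'
#' @param true_ratio Named numeric vector of true activity ratios (the names
#'   become sample labels). WT and knock-out control traces are always added
#'   under labels `"WT"` and `"KO"`.
#' @param wt_rate,ko_rate Fluorescence slopes (a.u./min) of the wild-type and
#'   knock-out controls; `wt_rate > ko_rate >= 0`.
#' @param noise_cv Replicate-level coefficient of variation on the rate.
#' @param saturation_time Time (min) at which the trace plateaus.
#' @param replicates Replicates per sample.
#' @param times Sampling times in minutes (default 0..30 at 1 min).
#' @param baseline Fluorescence offset, a.u.
#' @param seed Optional RNG seed.
#' @return List with `traces` (long data frame: `sample`, `replicate`,
#'   `time_min`, `intensity`) and `truth` (true ratios and rates).
#' @export
gen_kinetic_traces <- function(true_ratio, wt_rate = 100, ko_rate = 5,
                               noise_cv = 0, saturation_time = Inf,
                               replicates = 3, times = seq(0, 30, by = 1),
                               baseline = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!(wt_rate > ko_rate) || ko_rate < 0) {
    stop("need wt_rate > ko_rate >= 0")
  }
  if (is.null(names(true_ratio)) && length(true_ratio) > 0) {
    names(true_ratio) <- paste0("V", seq_along(true_ratio))
  }
  rates <- c(WT = wt_rate, KO = ko_rate,
             ko_rate + true_ratio * (wt_rate - ko_rate))
  traces <- do.call(rbind, lapply(names(rates), function(s) {
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      rate <- rates[[s]] * (1 + stats::rnorm(1, 0, noise_cv))
      data.frame(sample = s, replicate = r, time_min = times,
                 intensity = baseline + rate * pmin(times, saturation_time),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(traces = traces,
       truth = list(true_ratio = true_ratio, wt_rate = wt_rate,
                    ko_rate = ko_rate, rates = rates,
                    noise_cv = noise_cv, saturation_time = saturation_time))
}

#' Toy protein structure with controlled side-chain geometry
#'
#' Places residues along the x axis with one side-chain heavy atom each, at
#' controlled x positions, so that every inter-side-chain distance is known
#' analytically (the distance between side-chain anchors i and j is
#' `|x_i - x_j|` Angstrom). The focal residue is written as a lysine whose
#' single side-chain atom is its terminal amine NZ; all others are written
#' with a single CB atom. Backbone atoms are placed in a separate plane 5
#' Angstrom away so they never enter side-chain distance calculations.
#'
#' @param sidechain_x Numeric vector of side-chain anchor x positions
#'   (Angstrom), one per residue.
#' @param focal Index (1-based) of the residue written as the focal lysine.
#' @param path Optional path; when given, PDB text is written there.
#' @return List with `structure` (a `varsite_structure`), `pdb_text`
#'   (character vector of PDB lines) and `truth` (pairwise side-chain
#'   distance matrix).
#' @export
gen_toy_structure <- function(sidechain_x, focal = 1L, path = NULL) {
  n <- length(sidechain_x)
  stopifnot(n >= 1, focal >= 1, focal <= n)
  lines <- character()
  serial <- 0L
  add <- function(name, res_name, res_no, x, y, z, element) {
    serial <<- serial + 1L
    pdb_atom_line(serial, name, res_name, "A", res_no, x, y, z, element)
  }
  for (i in seq_len(n)) {
    res_name <- if (i == focal) "LYS" else "ALA"
    x <- sidechain_x[i]
    lines <- c(lines,
               add("N", res_name, i, x - 0.5, -5, 0, "N"),
               add("CA", res_name, i, x, -5, 0, "C"),
               add("C", res_name, i, x + 0.5, -5, 0, "C"),
               add("O", res_name, i, x + 0.5, -6, 0, "O"))
    sc_name <- if (i == focal) "NZ" else "CB"
    sc_elem <- if (i == focal) "N" else "C"
    lines <- c(lines, add(sc_name, res_name, i, x, 0, 0, sc_elem))
  }
  lines <- c(lines, "END")
  tmp <- path
  if (is.null(tmp)) tmp <- tempfile(fileext = ".pdb")
  writeLines(lines, tmp)
  st <- read_structure(tmp)
  if (is.null(path)) unlink(tmp)
  dist_mat <- abs(outer(sidechain_x, sidechain_x, "-"))
  dimnames(dist_mat) <- list(seq_len(n), seq_len(n))
  list(structure = st, pdb_text = lines, truth = list(distances = dist_mat,
                                                      focal = focal))
}

# geometry helpers for the toy trajectory ------------------------------------

toy_trajectory_topology <- function(n_residues) {
  # each residue: backbone N/CA/C/O plus a hydroxyl-like side chain
  # OG (donor/acceptor heavy atom) and its hydrogen HG
  atoms <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
    data.frame(
      atom_name = c("N", "CA", "C", "O", "OG", "HG"),
      element = c("N", "C", "C", "O", "O", "H"),
      res_name = "SER", res_no = i, chain = "A",
      stringsAsFactors = FALSE)
  }))
  atoms$sidechain <- is_sidechain_atom(atoms$atom_name, atoms$element)
  atoms
}

toy_reference_coords <- function(atoms, spacing = 0.8) {
  # nm; residues along x, side chains along +y
  n <- nrow(atoms)
  xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    res <- atoms$res_no[i]
    base <- c((res - 1) * spacing, 0, 0)
    offset <- switch(atoms$atom_name[i],
                     "N"  = c(-0.05, -0.30, 0),
                     "CA" = c(0, -0.30, 0),
                     "C"  = c(0.05, -0.30, 0),
                     "O"  = c(0.05, -0.40, 0),
                     "OG" = c(0, 0.20, 0),
                     "HG" = c(0, 0.30, 0))
    xyz[i, ] <- base + offset
  }
  xyz
}

#' Toy MD trajectory with planted hydrogen bonds and fluctuations
#'
#' Builds a small serine-like peptide (each residue carries one hydroxyl
#' side chain: heavy atom OG plus hydrogen HG) and a frame series in which
#' (i) scheduled residue pairs are placed in ideal hydrogen-bond geometry
#' (donor-acceptor distance 0.29 nm, hydrogen-donor-acceptor angle 10
#' degrees) in the scheduled frames and well outside the distance cutoff
#' (0.45 nm) otherwise, and (ii) the side-chain atoms of unscheduled
#' residues fluctuate isotropically with per-coordinate standard deviation
#' `sigma` nm around the reference while the backbone stays fixed, so
#' superposition onto the reference is exact and side-chain RMSD statistics
#' have a closed form.
#'
#' @param n_residues Number of residues.
#' @param n_frames Number of frames.
#' @param dt_ps Time step between frames, ps.
#' @param sigma Per-coordinate side-chain fluctuation (nm); scalar or one
#'   value per residue.
#' @param hbond_schedule List of `list(pair = c(i, j), frames = <indices>)`
#'   entries: residue `i` donates to residue `j` in the listed frames. Pairs
#'   must not share residues with each other or with fluctuating residues'
#'   scheduled geometry.
#' @param replicate Replicate identifier stored on the trajectory.
#' @param seed Optional RNG seed.
#' @return List with `trajectory` (a `varsite_trajectory`) and `truth`
#'   (scheduled occupancy per pair, sigma per residue, reference coords).
#' @export
gen_toy_trajectory <- function(n_residues = 4, n_frames = 100, dt_ps = 10,
                               sigma = 0, hbond_schedule = list(),
                               replicate = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  atoms <- toy_trajectory_topology(n_residues)
  ref <- toy_reference_coords(atoms)
  sigma <- rep_len(sigma, n_residues)
  scheduled <- unique(unlist(lapply(hbond_schedule, `[[`, "pair")))
  if (length(scheduled) != 2L * length(hbond_schedule)) {
    stop("hbond_schedule pairs must not share residues")
  }
  coords <- array(NA_real_, dim = c(nrow(atoms), 3L, n_frames))
  idx_of <- function(res, name) which(atoms$res_no == res &
                                        atoms$atom_name == name)
  # hydrogen direction at 10 degrees from the donor-acceptor axis (+y)
  hdir <- c(sin(10 * pi / 180), cos(10 * pi / 180), 0)
  for (f in seq_len(n_frames)) {
    xyz <- ref
    for (sch in hbond_schedule) {
      don <- sch$pair[1]; acc <- sch$pair[2]
      d_og <- idx_of(don, "OG"); d_hg <- idx_of(don, "HG")
      a_og <- idx_of(acc, "OG"); a_hg <- idx_of(acc, "HG")
      p <- ref[d_og, ]
      dist <- if (f %in% sch$frames) 0.29 else 0.45
      xyz[d_hg, ] <- p + 0.10 * hdir
      xyz[a_og, ] <- p + c(0, dist, 0)
      # point the acceptor's own hydrogen away so only one bond forms
      xyz[a_hg, ] <- p + c(0, dist + 0.10, 0)
    }
    for (r in setdiff(seq_len(n_residues), scheduled)) {
      if (sigma[r] > 0) {
        sel <- which(atoms$res_no == r & atoms$sidechain)
        xyz[sel, ] <- xyz[sel, ] +
          matrix(stats::rnorm(length(sel) * 3, 0, sigma[r]), ncol = 3)
      }
    }
    coords[, , f] <- xyz
  }
  traj <- new_trajectory(atoms, coords, times = (seq_len(n_frames) - 1) * dt_ps,
                         replicate = replicate)
  occupancy <- vapply(hbond_schedule, function(sch) {
    length(intersect(sch$frames, seq_len(n_frames))) / n_frames
  }, numeric(1))
  list(trajectory = traj,
       truth = list(occupancy = occupancy, schedule = hbond_schedule,
                    sigma = sigma, reference = ref))
}

#' Synthetic protein family with controlled identity to a root sequence
#'
#' Generates a root amino-acid sequence and clades of descendants carrying an
#' exact number of random substitutions, so each member's identity to the
#' root is controlled exactly (`round((1 - identity) * length)` positions
#' mutated). Optionally plants a chosen residue letter at a designated
#' reference position in selected members, emulating orthologs that carry an
#' aspartate at the position aligned with a catalytic lysine. Sequences are
#' generated without indels, so they are mutually aligned as-is and can be
#' used directly as an MSA.
#'
#' @param root_length Length of the root sequence.
#' @param clades List of `list(n = <members>, identity = <fraction>)`.
#' @param planted Optional `list(position, letter, members)` where `members`
#'   are sequence ids (or a count of members drawn from the last clade).
#' @param root_id Identifier of the root record (included in the output).
#' @param seed Optional RNG seed.
#' @return List with `sequences` (named character vector, root first),
#'   `msa` (same, since generation is indel-free), and `truth`
#'   (identity-to-root per member, planted member ids, reference position).
#' @export
gen_sequence_family <- function(root_length = 300,
                                clades = list(list(n = 10, identity = 0.6)),
                                planted = NULL, root_id = "ROOT",
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  root <- sample(aa, root_length, replace = TRUE)
  if (!is.null(planted)) root[planted$position] <- "K"
  seqs <- list()
  seqs[[root_id]] <- root
  for (ci in seq_along(clades)) {
    cl <- clades[[ci]]
    n_mut <- round((1 - cl$identity) * root_length)
    for (m in seq_len(cl$n)) {
      s <- root
      pos <- sample.int(root_length, n_mut)
      s[pos] <- vapply(pos, function(p) {
        # at the planted column, random substitutions avoid the planted
        # letter so its count stays exactly as designed
        forbid <- root[p]
        if (!is.null(planted) && p == planted$position) {
          forbid <- c(forbid, planted$letter)
        }
        sample(setdiff(aa, forbid), 1)
      }, character(1))
      seqs[[sprintf("C%d_%02d", ci, m)]] <- s
    }
  }
  planted_members <- character()
  if (!is.null(planted)) {
    members <- planted$members
    if (is.numeric(members) && length(members) == 1L) {
      last <- sprintf("C%d_%02d", length(clades),
                      seq_len(clades[[length(clades)]]$n))
      members <- utils::head(last, members)
    }
    for (m in members) {
      seqs[[m]][planted$position] <- planted$letter
    }
    planted_members <- members
  }
  sequences <- vapply(seqs, paste, character(1), collapse = "")
  identity_to_root <- vapply(seqs, function(s) mean(s == root), numeric(1))
  list(sequences = sequences, msa = sequences,
       truth = list(identity_to_root = identity_to_root,
                    planted_members = planted_members,
                    position = if (is.null(planted)) NULL else planted$position,
                    letter = if (is.null(planted)) NULL else planted$letter))
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write pairwise hits in 12-column BLAST tabular format
#'
#' @param hits Data frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `e_value` (and optionally
#'   `bit_score`).
#' @param path Output path.
#' @export
write_blast_tabular <- function(hits, path) {
  n <- nrow(hits)
  bits <- if ("bit_score" %in% names(hits)) hits$bit_score else rep(0, n)
  tab <- data.frame(hits$query_id, hits$subject_id, hits$percent_identity,
                    hits$alignment_length, 0L, 0L, 1L, hits$alignment_length,
                    1L, hits$alignment_length,
                    format(hits$e_value, scientific = TRUE), bits)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Full synthetic study bundle for the end-to-end pipeline
#'
#' Writes the three CSV inputs the pipeline consumes (melt spectra, kinetic
#' traces, variant table) for a panel of enzyme variants with planted
#' melting temperatures, unfolding red-shifts and activity ratios spanning
#' every fitness class, including a stabilised double mutant with a planted
#' epistatic deviation. Study conditions mirror the assays emulated:
#' triplicate melts at 0.1 nm barycentric-mean noise over a 25-90 degC ramp,
#' and triplicate 30-min kinetic traces at 5% rate noise with late
#' saturation.
#'
#' @param dir Output directory (created if needed).
#' @param seed RNG seed.
#' @param replicates Replicates per assay.
#' @param melt_noise_sd Barycentric-mean noise, nm.
#' @param rate_noise_cv Rate coefficient of variation.
#' @return List with `config` (ready for [run_pipeline()]) and `truth`
#'   (planted per-variant metrics, expected classes and expected epistasis
#'   deviations).
#' @export
gen_variant_bundle <- function(dir, seed = 1, replicates = 3,
                               melt_noise_sd = 0.1, rate_noise_cv = 0.05) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  panel <- data.frame(
    name = c("WT", "K41D", "A201R", "A201K", "A201G", "K41A", "K41E",
             "A201Q", "K41D-A201R"),
    mutations = c("", "K41D", "A201R", "A201K", "A201G", "K41A", "K41E",
                  "A201Q", "K41D-A201R"),
    tm1 = c(60, 54, 60, 53, 57, 59, 52, 52, 58),
    red_shift = c(7.8, 7.8, 7.8, 7.8, 7.8, 7.8, 7.8, 5.0, 7.8),
    ratio = c(1, 0.05, 1.7, 1, 0.51, 0, 0, 0, 1.7),
    stringsAsFactors = FALSE)
  # expected additive dTm for the double: K41D (-6) + A201R (0) = -6;
  # planted observed is -2, so the planted epistatic deviation is +4
  panel$expected_deviation <- 0
  panel$expected_deviation[panel$name == "K41D-A201R"] <- 4

  spectra <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      g <- gen_melt_spectra(tm1 = panel$tm1[i], a = 2, bcm_n = 360 - panel$red_shift[i],
                            bcm_d = 360, noise_sd = melt_noise_sd,
                            seed = seed * 1000 + i * 10 + r)
      cbind(variant = panel$name[i], replicate = r, g$spectra)
    }))
  }))
  utils::write.csv(spectra, file.path(dir, "melt_spectra.csv"),
                   row.names = FALSE)

  ratios <- stats::setNames(panel$ratio[panel$name != "WT"],
                            panel$name[panel$name != "WT"])
  k <- gen_kinetic_traces(ratios, wt_rate = 100, ko_rate = 5,
                          noise_cv = rate_noise_cv, saturation_time = 20,
                          replicates = replicates, seed = seed + 1)
  utils::write.csv(k$traces, file.path(dir, "traces.csv"), row.names = FALSE)

  utils::write.csv(panel[, c("name", "mutations")],
                   file.path(dir, "variants.csv"), row.names = FALSE)

  th <- classification_thresholds()
  panel$below_detection <- panel$ratio == 0
  panel$class <- vapply(seq_len(nrow(panel)), function(i) {
    classify(panel$tm1[i], panel$ratio[i], panel$red_shift[i],
             panel$below_detection[i], panel$tm1[panel$name == "WT"],
             th)$class
  }, character(1))
  config <- list(melt_spectra = file.path(dir, "melt_spectra.csv"),
                 activity_traces = file.path(dir, "traces.csv"),
                 variants = file.path(dir, "variants.csv"),
                 output_dir = file.path(dir, "out"),
                 wt_label = "WT", ko_label = "KO", seed = seed)
  list(config = config, truth = panel)
}
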