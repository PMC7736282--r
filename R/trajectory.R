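#' Construct a trajectory object
#'
#' Internal coordinates are in nanometres and times in picoseconds.
#'
#' @param atoms Atom table (`atom_name`, `element`, `res_name`, `res_no`,
#'   `chain`, `sidechain`).
#' @param coords Numeric array of dimension `n_atoms x 3 x n_frames`, nm.
#' @param times Frame time stamps, ps (strictly increasing).
#' @param replicate Replicate identifier.
#' @return A `varsite_trajectory` list.
#' @export
new_trajectory <- function(atoms, coords, times, replicate = 1L) {
  stopifnot(is.data.frame(atoms), length(dim(coords)) == 3L,
            dim(coords)[1] == nrow(atoms), dim(coords)[2] == 3L,
            dim(coords)[3] == length(times))
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  obj <- list(atoms = atoms, coords = coords, times = as.numeric(times),
              replicate = replicate)
  class(obj) <- "varsite_trajectory"
  obj
}

n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Read an MD trajectory from topology + coordinate files
#'
#' The topology is a PDB file (hydrogens are kept: hydrogen-bond detection
#' needs them). Frames come from a multi-model PDB or a DCD file; both store
#' Angstrom coordinates, which are converted to nanometres internally.
#'
#' @param topology Path to a topology PDB.
#' @param frames Path to a multi-model PDB (`.pdb`) or DCD (`.dcd`) file.
#' @param dt_ps Time between frames, ps (used to build time stamps).
#' @param replicate Replicate identifier for this file.
#' @return A `varsite_trajectory`.
#' @export
read_trajectory <- function(topology, frames, dt_ps = 1, replicate = 1L) {
  atoms <- read_structure(topology, include_hydrogens = TRUE,
                          include_hetatm = TRUE)
  ext <- tolower(tools::file_ext(frames))
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(frames, verbose = FALSE)
  } else {
    pdb <- suppressWarnings(bio3d::read.pdb(frames, multi = TRUE,
                                            verbose = FALSE))
    xyz <- pdb$xyz
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atoms)) {
    stop("atom-count mismatch: topology has ", nrow(atoms),
         " atoms but frames have ", ncol(xyz) / 3)
  }
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nrow(atoms), 3L, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) / 10
  }
  new_trajectory(as.data.frame(atoms), coords,
                 times = (seq_len(nf) - 1) * dt_ps, replicate = replicate)
}

#' Hydrogen-bond geometric criteria
#'
#' Defaults follow the widely used MD convention: donor-acceptor distance at
#' most 0.35 nm and hydrogen-donor-acceptor angle at most 30 degrees.
#'
#' @param max_distance Maximum donor-acceptor distance, nm.
#' @param max_angle Maximum hydrogen-donor-acceptor angle, degrees.
#' @return A `varsite_hbond_criteria` list.
#' @export
hbond_criteria <- function(max_distance = 0.35, max_angle = 30) {
  stopifnot(max_distance > 0, max_angle > 0, max_angle <= 90)
  obj <- list(max_distance = max_distance, max_angle = max_angle)
  class(obj) <- "varsite_hbond_criteria"
  obj
}

# map each hydrogen to its covalently bonded heavy atom (nearest heavy atom
# within 0.12 nm); returns integer vector over atoms (NA for non-H)
assign_hydrogens <- function(atoms, xyz) {
  h_idx <- which(toupper(atoms$element) == "H")
  heavy <- which(toupper(atoms$element) != "H")
  parent <- rep(NA_integer_, nrow(atoms))
  for (h in h_idx) {
    d2 <- colSums((t(xyz[heavy, , drop = FALSE]) - xyz[h, ])^2)
    j <- which.min(d2)
    if (length(j) && d2[j] <= 0.12^2) parent[h] <- heavy[j]
  }
  parent
}

#' Detect hydrogen bonds in a single frame
#'
#' A bond donor-H...acceptor is reported when the donor-acceptor distance is
#' at most `criteria$max_distance` and the hydrogen-donor-acceptor angle is
#' at most `criteria$max_angle`. Donors are N/O heavy atoms carrying at least
#' one covalently bonded hydrogen (hydrogens are attached to their nearest
#' heavy atom within 0.12 nm); acceptors are N/O heavy atoms. When the
#' topology carries no hydrogens a heavy-atom-only proxy is used instead
#' (distance criterion plus donor-acceptor-antecedent angle >= 90 degrees);
#' this proxy is not equivalent to the hydrogen-resolved criterion and the
#' result is flagged accordingly.
#'
#' @param atoms Atom table.
#' @param xyz `n_atoms x 3` coordinate matrix, nm.
#' @param donors,acceptors Optional integer atom indices restricting the
#'   search; defaults to all eligible N/O atoms.
#' @param criteria A [hbond_criteria()] object.
#' @return Data frame with columns `donor`, `hydrogen`, `acceptor` (atom
#'   indices; `hydrogen` is `NA` in heavy-only mode), `distance` (nm) and
#'   `angle` (degrees). Attribute `mode` is `"hydrogen"` or `"heavy_only"`.
#' @export
detect_hbonds <- function(atoms, xyz, donors = NULL, acceptors = NULL,
                          criteria = hbond_criteria()) {
  polar <- which(toupper(atoms$element) %in% c("N", "O"))
  parent <- assign_hydrogens(atoms, xyz)
  # hydrogen-resolved mode whenever the topology carries hydrogens
  has_h <- any(toupper(atoms$element) == "H")
  if (is.null(donors)) {
    donors <- if (has_h) intersect(polar, parent[!is.na(parent)]) else polar
  } else {
    donors <- intersect(donors, polar)
  }
  if (is.null(acceptors)) acceptors <- polar else
    acceptors <- intersect(acceptors, polar)
  empty <- data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric())
  if (length(donors) == 0L || length(acceptors) == 0L) {
    warning("no donors or acceptors in selection")
    attr(empty, "mode") <- if (has_h) "hydrogen" else "heavy_only"
    return(empty)
  }
  res <- empty
  if (has_h) {
    h_of <- split(which(!is.na(parent)), parent[!is.na(parent)])
    for (d in donors) {
      hs <- h_of[[as.character(d)]]
      if (is.null(hs)) next
      for (acc in setdiff(acceptors, d)) {
        v_da <- xyz[acc, ] - xyz[d, ]
        dist <- sqrt(sum(v_da^2))
        if (dist > criteria$max_distance || dist == 0) next
        for (h in hs) {
          v_dh <- xyz[h, ] - xyz[d, ]
          cosang <- sum(v_dh * v_da) / (sqrt(sum(v_dh^2)) * dist)
          ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
          if (ang <= criteria$max_angle) {
            res <- rbind(res, data.frame(donor = d, hydrogen = h,
                                         acceptor = acc, distance = dist,
                                         angle = ang))
          }
        }
      }
    }
    attr(res, "mode") <- "hydrogen"
  } else {
    heavy <- which(toupper(atoms$element) != "H")
    for (d in donors) {
      for (acc in setdiff(acceptors, d)) {
        v_ad <- xyz[d, ] - xyz[acc, ]
        dist <- sqrt(sum(v_ad^2))
        if (dist > criteria$max_distance || dist == 0) next
        # acceptor antecedent: nearest covalently bonded heavy atom
        others <- setdiff(heavy, c(acc, d))
        ang <- NA_real_
        ok <- TRUE
        if (length(others)) {
          d2 <- colSums((t(xyz[others, , drop = FALSE]) - xyz[acc, ])^2)
          j <- others[which.min(d2)]
          if (min(d2) <= 0.17^2) {
            v_aaa <- xyz[j, ] - xyz[acc, ]
            cosang <- sum(v_ad * v_aaa) / sqrt(sum(v_ad^2) * sum(v_aaa^2))
            ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
            ok <- ang >= 90
          }
        }
        if (ok) {
          res <- rbind(res, data.frame(donor = d, hydrogen = NA_integer_,
                                       acceptor = acc, distance = dist,
                                       angle = ang))
        }
      }
    }
    attr(res, "mode") <- "heavy_only"
  }
  res
}

# side-chain-to-side-chain residue pair bonds in one frame
frame_residue_pairs <- function(trajectory, frame, residue_set, criteria) {
  atoms <- trajectory$atoms
  sel <- which(atoms$res_no %in% residue_set & atoms$sidechain)
  xyz <- trajectory$coords[, , frame]
  hb <- detect_hbonds(atoms, xyz, donors = sel, acceptors = sel,
                      criteria = criteria)
  if (nrow(hb) == 0L) return(hb)
  rd <- atoms$res_no[hb$donor]
  ra <- atoms$res_no[hb$acceptor]
  hb <- hb[rd != ra, , drop = FALSE]
  hb$res_a <- pmin(atoms$res_no[hb$donor], atoms$res_no[hb$acceptor])
  hb$res_b <- pmax(atoms$res_no[hb$donor], atoms$res_no[hb$acceptor])
  hb
}

as_trajectory_list <- function(trajectories) {
  if (inherits(trajectories, "varsite_trajectory")) list(trajectories)
  else trajectories
}

equilibration_start <- function(trajectory, equilibration,
                                window_ps = 1000, tol = 0.05) {
  if (identical(equilibration, "auto")) {
    detect_equilibration(trajectory, window_ps = window_ps, tol = tol)
  } else {
    sum(trajectory$times < equilibration) + 1L
  }
}

#' Detect the post-equilibration portion of a trajectory
#'
#' Operationalises "frames after the system reaches a steady-state RMSD":
#' computes the all-atom RMSD of each frame to the first frame (after
#' least-squares superposition), then returns the first frame index from
#' which the running mean of that series changes by less than `tol`
#' (relative) across a `window_ps` window. If the series never stabilises,
#' all frames are kept with a warning.
#'
#' @param trajectory A `varsite_trajectory`.
#' @param window_ps Window length, ps.
#' @param tol Relative change tolerance.
#' @return Integer index of the first retained frame.
#' @export
detect_equilibration <- function(trajectory, window_ps = 1000, tol = 0.05) {
  nf <- n_frames(trajectory)
  if (nf < 3L) return(1L)
  heavy <- which(toupper(trajectory$atoms$element) != "H")
  ref <- trajectory$coords[heavy, , 1]
  rmsd <- vapply(seq_len(nf), function(f) {
    kabsch_rmsd(ref, trajectory$coords[heavy, , f])
  }, numeric(1))
  # frame 1 is the reference itself (RMSD identically 0): exclude it from
  # the running mean so it cannot poison the relative-change test
  rm <- cumsum(rmsd[-1]) / seq_len(nf - 1L)
  dt <- mean(diff(trajectory$times))
  w <- max(1L, round(window_ps / dt))
  if (w >= nf - 1L) return(1L)
  floor_nm <- 1e-3
  for (t in seq_len(nf - 1L - w)) {
    change <- abs(rm[t + w] - rm[t]) / max(rm[t], floor_nm)
    if (change < tol) return(t)
  }
  warning("no steady-state RMSD detected; keeping all frames")
  1L
}

# Kabsch superposition RMSD of two n x 3 coordinate sets
kabsch_rmsd <- function(a, b) {
  fit <- kabsch_fit(a, b)
  sqrt(mean(rowSums((fit - a)^2)))
}

# superpose b onto a (both n x 3), returning transformed b
kabsch_fit <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  s <- svd(t(b0) %*% a0)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(b0 %*% t(rot), 2, ca, "+")
}

#' Hydrogen-bond occurrence network over trajectories
#'
#' For every unordered pair of residues in `residue_set`, counts the frames
#' (pooled over replicate trajectories, after an equilibration cut) that
#' contain at least one side-chain-to-side-chain hydrogen bond between the
#' pair, in either donor/acceptor direction. Edge occupancy is the count
#' divided by the number of frames analysed.
#'
#' @param trajectories A `varsite_trajectory` or list of them (replicates).
#' @param residue_set Integer residue numbers to analyse.
#' @param criteria [hbond_criteria()].
#' @param equilibration `"auto"` (steady-state RMSD rule, see
#'   [detect_equilibration()]), or a time in ps before which frames are
#'   discarded (0 keeps everything).
#' @return A `varsite_hbond_network` list: `graph` (igraph, edge attributes
#'   `count` and `occupancy`), `pairs` (data frame with pooled and
#'   per-replicate counts) and `frames_analysed`.
#' @export
occurrence_network <- function(trajectories, residue_set,
                               criteria = hbond_criteria(),
                               equilibration = "auto") {
  trajectories <- as_trajectory_list(trajectories)
  stopifnot(length(trajectories) >= 1L)
  pair_counts <- list()
  frames_total <- 0L
  per_rep <- list()
  for (traj in trajectories) {
    start <- equilibration_start(traj, equilibration)
    frames <- seq(start, n_frames(traj))
    frames_total <- frames_total + length(frames)
    counts <- new.env(parent = emptyenv())
    for (f in frames) {
      hb <- frame_residue_pairs(traj, f, residue_set, criteria)
      if (nrow(hb) == 0L) next
      for (key in unique(paste(hb$res_a, hb$res_b, sep = "-"))) {
        counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
      }
    }
    per_rep[[as.character(traj$replicate)]] <-
      list(counts = as.list(counts), frames = length(frames))
  }
  keys <- unique(unlist(lapply(per_rep, function(x) names(x$counts))))
  pairs <- if (length(keys)) {
    parts <- strsplit(keys, "-", fixed = TRUE)
    df <- data.frame(
      res_a = as.integer(vapply(parts, `[`, character(1), 1)),
      res_b = as.integer(vapply(parts, `[`, character(1), 2)))
    df$count <- vapply(keys, function(k) {
      sum(vapply(per_rep, function(x) {
        v <- x$counts[[k]]; if (is.null(v)) 0L else v
      }, integer(1)))
    }, integer(1))
    for (rep_id in names(per_rep)) {
      df[[paste0("count_rep_", rep_id)]] <- vapply(keys, function(k) {
        v <- per_rep[[rep_id]]$counts[[k]]; if (is.null(v)) 0L else v
      }, integer(1))
    }
    df$occupancy <- df$count / frames_total
    rownames(df) <- NULL
    df[order(-df$count), , drop = FALSE]
  } else {
    data.frame(res_a = integer(), res_b = integer(), count = integer(),
               occupancy = numeric())
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(residue_set),
                            name = as.character(sort(residue_set)))
  if (nrow(pairs)) {
    el <- rbind(as.character(pairs$res_a), as.character(pairs$res_b))
    g <- igraph::add_edges(g, as.vector(el))
    igraph::E(g)$count <- pairs$count
    igraph::E(g)$occupancy <- pairs$occupancy
  }
  out <- list(graph = g, pairs = pairs, frames_analysed = frames_total)
  class(out) <- "varsite_hbond_network"
  out
}

#' Per-frame hydrogen-bond counts between two residues
#'
#' Counts the simultaneous distinct hydrogen bonds (distinct donor-acceptor
#' atom pairs, either direction) between the side chains of two residues in
#' every frame, pooled over replicate trajectories.
#'
#' @inheritParams occurrence_network
#' @param res_a,res_b The two residue numbers.
#' @return List with `series` (data frame: `replicate`, `time`, `count`) and
#'   `summary` (median and interquartile range, pooled and per replicate).
#' @export
hbond_count_series <- function(trajectories, res_a, res_b,
                               criteria = hbond_criteria(),
                               equilibration = 0) {
  trajectories <- as_trajectory_list(trajectories)
  series <- do.call(rbind, lapply(trajectories, function(traj) {
    start <- equilibration_start(traj, equilibration)
    frames <- seq(start, n_frames(traj))
    cnt <- vapply(frames, function(f) {
      hb <- frame_residue_pairs(traj, f, c(res_a, res_b), criteria)
      if (nrow(hb) == 0L) return(0L)
      nrow(unique(hb[, c("donor", "acceptor")]))
    }, integer(1))
    data.frame(replicate = traj$replicate, time = traj$times[frames],
               count = cnt)
  }))
  summ <- summarise_by_replicate(series, "count")
  list(series = series, summary = summ)
}

summarise_by_replicate <- function(series, col) {
  per <- lapply(split(series[[col]], series$replicate), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(median = q[2], q25 = q[1], q75 = q[3], iqr = q[3] - q[1],
               n = length(v))
  })
  out <- do.call(rbind, per)
  out <- cbind(replicate = names(per), out)
  vall <- series[[col]]
  q <- stats::quantile(vall, c(0.25, 0.5, 0.75), names = FALSE)
  pooled <- data.frame(replicate = "pooled", median = q[2], q25 = q[1],
                       q75 = q[3], iqr = q[3] - q[1], n = length(vall))
  rownames(out) <- NULL
  rbind(out, pooled)
}

#' Distance between two named atoms along a trajectory
#'
#' @param trajectory A `varsite_trajectory`.
#' @param res_a,atom_a Residue number and atom name of the first atom.
#' @param res_b,atom_b Residue number and atom name of the second atom.
#' @return Data frame with `time` (ps) and `distance` (nm).
#' @export
atom_distance_series <- function(trajectory, res_a, atom_a, res_b, atom_b) {
  i <- resolve_atom(trajectory$atoms, res_a, atom_a)
  j <- resolve_atom(trajectory$atoms, res_b, atom_b)
  if (i == j) stop("the two selectors resolve to the same atom")
  d <- vapply(seq_len(n_frames(trajectory)), function(f) {
    sqrt(sum((trajectory$coords[i, , f] - trajectory$coords[j, , f])^2))
  }, numeric(1))
  data.frame(time = trajectory$times, distance = d)
}

resolve_atom <- function(atoms, res_no, atom_name) {
  hits <- which(atoms$res_no == res_no & atoms$atom_name == atom_name)
  if (length(hits) == 0L) {
    stop("no atom '", atom_name, "' in residue ", res_no)
  }
  if (length(hits) > 1L) {
    stop("ambiguous atom selector (residue ", res_no, ", atom ", atom_name,
         "): matches atoms ", paste(hits, collapse = ", "))
  }
  hits
}

#' Side-chain RMSD series for a residue set
#'
#' Each frame is least-squares superposed onto the reference over
#' `fit_selection` (default: all backbone heavy atoms, so internal side-chain
#' motion is retained and low RMSD reads as active-site rigidity), then the
#' RMSD over the side-chain heavy atoms of `residue_set` is computed.
#'
#' @inheritParams occurrence_network
#' @param residue_set Residue numbers whose side chains are measured.
#' @param reference `"first"` (first frame of the first trajectory) or an
#'   `n_atoms x 3` coordinate matrix in nm.
#' @param fit_selection `"backbone"`, `"local"` (backbone heavy atoms of
#'   `residue_set` only) or an integer vector of atom indices.
#' @return A `varsite_rmsd` list: `series` (data frame `replicate`, `time`,
#'   `rmsd` in nm) and `summary` (median/IQR per replicate and pooled).
#' @export
sidechain_rmsd_series <- function(trajectories, residue_set,
                                  reference = "first",
                                  fit_selection = "backbone",
                                  equilibration = 0) {
  trajectories <- as_trajectory_list(trajectories)
  atoms <- trajectories[[1]]$atoms
  for (r in residue_set) {
    sc <- which(atoms$res_no == r & atoms$sidechain)
    if (length(sc) == 0L) {
      stop("residue ", r, " has no side-chain heavy atoms (glycine?)")
    }
  }
  measure <- which(atoms$res_no %in% residue_set & atoms$sidechain)
  if (is.character(fit_selection)) {
    backbone <- atoms$atom_name %in% c("N", "CA", "C", "O") &
      toupper(atoms$element) != "H"
    fit_idx <- switch(fit_selection,
                      backbone = which(backbone),
                      local = which(backbone & atoms$res_no %in% residue_set),
                      stop("unknown fit_selection: ", fit_selection))
  } else {
    fit_idx <- fit_selection
  }
  if (length(fit_idx) < 3L) stop("fit selection needs at least 3 atoms")
  ref <- if (identical(reference, "first")) {
    trajectories[[1]]$coords[, , 1]
  } else {
    reference
  }
  series <- do.call(rbind, lapply(trajectories, function(traj) {
    start <- equilibration_start(traj, equilibration)
    frames <- seq(start, n_frames(traj))
    rmsd <- vapply(frames, function(f) {
      xyz <- traj$coords[, , f]
      # superpose on the fit selection, then apply the same rigid
      # transform to the measured atoms
      tr <- kabsch_transform(ref[fit_idx, , drop = FALSE],
                             xyz[fit_idx, , drop = FALSE])
      moved <- sweep(sweep(xyz[measure, , drop = FALSE], 2, tr$cb) %*%
                       t(tr$rot), 2, tr$ca, "+")
      sqrt(mean(rowSums((moved - ref[measure, , drop = FALSE])^2)))
    }, numeric(1))
    data.frame(replicate = traj$replicate, time = traj$times[frames],
               rmsd = rmsd)
  }))
  out <- list(series = series, summary = summarise_by_replicate(series, "rmsd"))
  class(out) <- "varsite_rmsd"
  out
}

kabsch_transform <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  s <- svd(t(b0) %*% a0)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rot = rot, ca = ca, cb = cb)
}
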