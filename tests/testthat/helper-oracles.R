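# Independent brute-force oracles used to cross-check the implementation.

# all-pairs distance scan: residues with any side-chain heavy atom within
# cutoff of any atom in the focal selection
oracle_sidechain_neighbors <- function(st, res_no, cutoff,
                                       focal_atom = "sidechain") {
  focal <- st[st$res_no == res_no, ]
  focal <- if (identical(focal_atom, "sidechain")) focal[focal$sidechain, ]
           else focal[focal$atom_name == focal_atom, ]
  found <- integer()
  for (i in which(st$sidechain & st$res_no != res_no)) {
    for (j in seq_len(nrow(focal))) {
      d <- sqrt(sum((c(st$x[i], st$y[i], st$z[i]) -
                       c(focal$x[j], focal$y[j], focal$z[j]))^2))
      if (d <= cutoff) found <- c(found, st$res_no[i])
    }
  }
  sort(unique(found))
}

# naive triple loop over (hydrogen, donor, acceptor)
oracle_hbonds <- function(atoms, xyz, criteria = hbond_criteria()) {
  heavy <- which(toupper(atoms$element) != "H")
  hs <- which(toupper(atoms$element) == "H")
  polar <- which(toupper(atoms$element) %in% c("N", "O"))
  out <- NULL
  for (h in hs) {
    dists <- sapply(heavy, function(i) sqrt(sum((xyz[h, ] - xyz[i, ])^2)))
    parent <- heavy[which.min(dists)]
    if (min(dists) > 0.12) next
    if (!parent %in% polar) next
    for (acc in setdiff(polar, parent)) {
      v_da <- xyz[acc, ] - xyz[parent, ]
      dist <- sqrt(sum(v_da^2))
      if (dist == 0 || dist > criteria$max_distance) next
      v_dh <- xyz[h, ] - xyz[parent, ]
      ang <- acos(min(max(sum(v_dh * v_da) /
                            (sqrt(sum(v_dh^2)) * dist), -1), 1)) * 180 / pi
      if (ang <= criteria$max_angle) {
        out <- rbind(out, c(parent, h, acc))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer()))
  }
  out <- as.data.frame(out)
  names(out) <- c("donor", "hydrogen", "acceptor")
  out[order(out$donor, out$hydrogen, out$acceptor), ]
}

random_frame <- function(n_atoms = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  atoms <- data.frame(
    atom_name = paste0("X", seq_len(n_atoms)),
    element = sample(c("C", "N", "O", "H"), n_atoms, replace = TRUE),
    res_name = "UNK", res_no = seq_len(n_atoms), chain = "A",
    stringsAsFactors = FALSE)
  atoms$sidechain <- TRUE
  xyz <- matrix(runif(n_atoms * 3, 0, 1.2), ncol = 3)
  # bond most hydrogens to a random heavy atom so donor geometry occurs
  heavy <- which(atoms$element != "H")
  for (h in which(atoms$element == "H")) {
    if (length(heavy) && runif(1) < 0.8) {
      p <- sample(heavy, 1)
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      xyz[h, ] <- xyz[p, ] + runif(1, 0.08, 0.11) * dir
    }
  }
  list(atoms = atoms, xyz = xyz)
}

# simple threshold filter over a hit table
oracle_ssn_edges <- function(hits, threshold) {
  keep <- hits$e_value < threshold & hits$query_id != hits$subject_id
  e <- hits[keep, c("query_id", "subject_id")]
  keys <- apply(e, 1, function(r) paste(sort(r), collapse = "|"))
  sort(unique(keys))
}

ssn_edge_keys <- function(g) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) return(character())
  sort(unique(apply(el, 1, function(r) paste(sort(r), collapse = "|"))))
}

random_hits <- function(n_nodes = 20, n_hits = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- paste0("S", seq_len(n_nodes))
  data.frame(
    query_id = sample(ids, n_hits, replace = TRUE),
    subject_id = sample(ids, n_hits, replace = TRUE),
    percent_identity = runif(n_hits, 10, 100),
    alignment_length = sample(100:400, n_hits, replace = TRUE),
    e_value = 10^runif(n_hits, -60, 0),
    stringsAsFactors = FALSE)
}

# rigid motion helper: random rotation + translation
random_rigid_motion <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- matrix(rnorm(9), 3)
  rot <- qr.Q(qr(q))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  list(rot = rot, shift = rnorm(3, 0, 2))
}

apply_rigid <- function(xyz, motion) {
  sweep(xyz %*% t(motion$rot), 2, motion$shift, "+")
}
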