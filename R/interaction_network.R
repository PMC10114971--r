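# Geometric classification of non-covalent contacts — hydrogen bonds,
# salt bridges, pi-pi stacking, metal coordination — per frame, with
# occupancy aggregation over trajectories and between-state network diffs.
# Criteria follow the conventions of rule-based interaction profilers; the
# hydrogen-bond thresholds (donor-acceptor < 3.5 A, angle at hydrogen
# > 120 degrees, both strict) are the common occupancy-table definition.

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
          "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

residue_code <- function(resname) {
  i <- match(toupper(resname), .aa3)
  ifelse(is.na(i), toupper(resname), .aa1[i])
}

# donor (heavy, hydrogen) pairs and acceptor atoms per residue template
.backbone_donor <- list(c("N", "H"))
.backbone_acceptor <- "O"
.hbond_templates <- local({
  t <- list()
  for (r in .aa3) t[[r]] <- list(donors = .backbone_donor,
                                 acceptors = .backbone_acceptor)
  t$PRO$donors <- list()  # no amide H
  add <- function(res, donors = list(), acceptors = character(0)) {
    t[[res]]$donors <<- c(t[[res]]$donors, donors)
    t[[res]]$acceptors <<- c(t[[res]]$acceptors, acceptors)
  }
  add("SER", list(c("OG", "HG")), "OG")
  add("THR", list(c("OG1", "HG1")), "OG1")
  add("TYR", list(c("OH", "HH")), "OH")
  add("CYS", list(c("SG", "HG")), "SG")
  add("ASN", list(c("ND2", "HD21"), c("ND2", "HD22")), "OD1")
  add("GLN", list(c("NE2", "HE21"), c("NE2", "HE22")), "OE1")
  add("LYS", list(c("NZ", "HZ1"), c("NZ", "HZ2"), c("NZ", "HZ3")))
  add("ARG", list(c("NE", "HE"), c("NH1", "HH11"), c("NH1", "HH12"),
                  c("NH2", "HH21"), c("NH2", "HH22")))
  add("HIS", list(c("ND1", "HD1"), c("NE2", "HE2")), c("ND1", "NE2"))
  add("TRP", list(c("NE1", "HE1")))
  add("ASP", acceptors = c("OD1", "OD2"))
  add("GLU", acceptors = c("OE1", "OE2"))
  t$GTP <- list(
    donors = list(c("O2'", "HO'2"), c("O3'", "HO'3"), c("N1", "H1"),
                  c("N2", "H21"), c("N2", "H22")),
    acceptors = c("N7", "O6", "N3", "O4'", "O5'", "O2'", "O3'",
                  "O1A", "O2A", "O3A", "O1B", "O2B", "O3B",
                  "O1G", "O2G", "O3G"))
  t$HOH <- list(donors = list(c("O", "H1"), c("O", "H2")), acceptors = "O")
  t$WAT <- t$HOH
  t
})

# charged-group atom sets per residue template
.charged_groups <- list(
  cation = list(LYS = list("NZ"), ARG = list(c("NH1", "NH2")),
                HIP = list(c("ND1", "NE2"))),
  anion = list(ASP = list(c("OD1", "OD2")), GLU = list(c("OE1", "OE2")),
               GTP = list(c("O1A", "O2A", "O3A"), c("O1B", "O2B", "O3B"),
                          c("O1G", "O2G", "O3G")))
)

.ring_templates <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  GTP = list(c("C4", "C5", "C6", "N1", "C2", "N3"),
             c("N9", "C8", "N7", "C5", "C4"))
)

#' Hydrogen-bond detection criteria
#' @param max_da_distance maximum donor-acceptor distance (A, strict `<`)
#' @param min_angle minimum angle at the hydrogen between the H-donor and
#'   H-acceptor directions (degrees, strict `>`)
#' @export
hbond_criteria <- function(max_da_distance = 3.5, min_angle = 120) {
  stopifnot(max_da_distance > 0, min_angle > 0, min_angle <= 180)
  structure(list(max_da_distance = max_da_distance, min_angle = min_angle),
            class = "hbond_criteria")
}

# per-residue template matches on a topology: donors (d_idx, h_idx) and
# acceptor indices
template_participants <- function(topology) {
  a <- topology$atoms
  donors <- NULL
  missing_h <- NULL
  acceptors <- integer(0)
  key <- paste(a$chain, a$residue_number)
  for (resk in unique(key)) {
    rows <- which(key == resk)
    rn <- toupper(a$residue_name[rows[1]])
    tpl <- .hbond_templates[[rn]]
    if (is.null(tpl)) next
    nm <- trimws(a$name[rows])
    for (dh in tpl$donors) {
      di <- rows[match(dh[1], nm)]
      hi <- rows[match(dh[2], nm)]
      if (is.na(di)) next
      if (is.na(hi)) {
        missing_h <- rbind(missing_h, c(di, NA))
      } else {
        donors <- rbind(donors, c(di, hi))
      }
    }
    acceptors <- c(acceptors, rows[stats::na.omit(match(tpl$acceptors, nm))])
  }
  list(donors = donors, missing_h = missing_h, acceptors = acceptors)
}

hbond_key <- function(a, di, hi, ai) {
  don <- paste0(residue_code(a$residue_name[di]), a$residue_number[di], "-",
                trimws(a$name[di]),
                if (!is.na(hi)) paste0("-", trimws(a$name[hi])) else "")
  acc <- paste0(residue_code(a$residue_name[ai]), a$residue_number[ai], "-",
                trimws(a$name[ai]))
  paste0(don, "..", acc)
}

#' Detect hydrogen bonds in one frame
#'
#' One record per donor/hydrogen/acceptor triple with donor-acceptor
#' distance below and angle at the hydrogen above the criteria (both
#' strict).  Donors and acceptors come from built-in residue templates
#' (20 amino acids, GTP, water) unless supplied explicitly.  Pairs within
#' the same residue are skipped.
#'
#' @param coords `N x 3` frame coordinates
#' @param topology matching [topology()]
#' @param criteria a [hbond_criteria()]
#' @param donors optional 2-column matrix of (donor, hydrogen) atom
#'   indices; hydrogen may be `NA` only with `heavy_fallback`
#' @param acceptors optional acceptor atom indices
#' @param heavy_fallback accept donor-acceptor pairs on distance alone
#'   when the donor hydrogen is absent (records flagged `no_angle`)
#' @return data.frame of interaction records (0 rows if none)
#' @export
detect_hbonds <- function(coords, topology, criteria = hbond_criteria(),
                          donors = NULL, acceptors = NULL,
                          heavy_fallback = FALSE) {
  coords <- as.matrix(coords)
  a <- topology$atoms
  if (is.null(donors) || is.null(acceptors)) {
    tp <- template_participants(topology)
    if (is.null(donors)) {
      donors <- tp$donors
      if (!is.null(tp$missing_h)) {
        if (heavy_fallback) donors <- rbind(donors, tp$missing_h)
        else stop("donor hydrogens missing from the structure; add them or ",
                  "enable heavy_fallback")
      }
      if (is.null(donors)) donors <- matrix(integer(0), 0, 2)
    }
    if (is.null(acceptors)) acceptors <- tp$acceptors
  }
  donors <- matrix(as.integer(donors), ncol = 2)
  out <- list()
  for (r in seq_len(nrow(donors))) {
    di <- donors[r, 1]; hi <- donors[r, 2]
    if (is.na(hi) && !heavy_fallback) {
      stop("donor hydrogen index is NA but heavy_fallback is disabled")
    }
    for (ai in acceptors) {
      if (ai == di || (!is.na(hi) && ai == hi)) next
      if (a$residue_number[ai] == a$residue_number[di] &&
          a$chain[ai] == a$chain[di]) next
      dda <- sqrt(sum((coords[di, ] - coords[ai, ])^2))
      if (!(dda < criteria$max_da_distance)) next
      if (is.na(hi)) {
        out[[length(out) + 1]] <- data.frame(
          kind = "hbond", key = hbond_key(a, di, hi, ai), distance = dda,
          angle = NA_real_, no_angle = TRUE, stringsAsFactors = FALSE)
        next
      }
      v1 <- coords[di, ] - coords[hi, ]
      v2 <- coords[ai, ] - coords[hi, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      if (ang > criteria$min_angle) {
        out[[length(out) + 1]] <- data.frame(
          kind = "hbond", key = hbond_key(a, di, hi, ai), distance = dda,
          angle = ang, no_angle = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(kind = character(0), key = character(0),
                      distance = numeric(0), angle = numeric(0),
                      no_angle = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

charged_group_indices <- function(topology) {
  a <- topology$atoms
  key <- paste(a$chain, a$residue_number)
  res <- list(cation = list(), anion = list())
  for (cls in c("cation", "anion")) {
    for (resk in unique(key)) {
      rows <- which(key == resk)
      rn <- toupper(a$residue_name[rows[1]])
      groups <- .charged_groups[[cls]][[rn]]
      if (is.null(groups)) next
      for (gi in seq_along(groups)) {
        nm <- trimws(a$name[rows])
        idx <- rows[stats::na.omit(match(groups[[gi]], nm))]
        if (length(idx) == 0) next
        label <- paste0(residue_code(rn), a$residue_number[rows[1]],
                        if (length(groups) > 1) paste0(".", gi) else "")
        res[[cls]][[label]] <- idx
      }
    }
  }
  res
}

#' Detect salt bridges in one frame
#'
#' Records every (cation-group centroid, anion-group centroid) pair within
#' the cutoff.  Groups come from residue templates (LYS/ARG/protonated HIS
#' cations; ASP/GLU carboxylates and the three GTP phosphate groups as
#' anions).
#'
#' @param coords `N x 3` frame coordinates
#' @param topology matching [topology()]
#' @param cutoff centroid-centroid cutoff (A)
#' @return data.frame of interaction records
#' @export
detect_salt_bridges <- function(coords, topology, cutoff = 5.5) {
  coords <- as.matrix(coords)
  groups <- charged_group_indices(topology)
  out <- list()
  for (cn in names(groups$cation)) {
    cc <- colMeans(coords[groups$cation[[cn]], , drop = FALSE])
    for (an in names(groups$anion)) {
      ac <- colMeans(coords[groups$anion[[an]], , drop = FALSE])
      d <- sqrt(sum((cc - ac)^2))
      if (d <= cutoff) {
        out[[length(out) + 1]] <- data.frame(
          kind = "salt_bridge", key = paste0(cn, "+..", an, "-"),
          distance = d, angle = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(kind = character(0), key = character(0),
                      distance = numeric(0), angle = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

ring_geometry <- function(coords, idx) {
  m <- coords[idx, , drop = FALSE]
  ctr <- colMeans(m)
  c0 <- sweep(m, 2, ctr)
  s <- svd(c0)
  normal <- s$v[, 3]
  rms_out <- sqrt(mean((c0 %*% normal)^2))
  list(center = ctr, normal = normal, rms_out = rms_out)
}

#' Detect pi-pi stacking interactions in one frame
#'
#' Aromatic rings from residue templates (PHE/TYR/HIS/TRP side chains and
#' the two GTP guanine rings).  A pair is recorded when the ring-centroid
#' distance is within the cutoff and the angle between ring normals is
#' either near-parallel (<= 30 degrees) or T-shaped (60-90 degrees).
#' Rings with RMS out-of-plane deviation above 0.3 A are skipped with a
#' warning.
#'
#' @param coords `N x 3` frame coordinates
#' @param topology matching [topology()]
#' @param max_dist centroid cutoff (A)
#' @return data.frame of interaction records with a `geometry` class tag
#' @export
detect_pi_pi <- function(coords, topology, max_dist = 5.5) {
  coords <- as.matrix(coords)
  a <- topology$atoms
  key <- paste(a$chain, a$residue_number)
  rings <- list()
  for (resk in unique(key)) {
    rows <- which(key == resk)
    rn <- toupper(a$residue_name[rows[1]])
    tpls <- .ring_templates[[rn]]
    if (is.null(tpls)) next
    nm <- trimws(a$name[rows])
    for (gi in seq_along(tpls)) {
      idx <- rows[match(tpls[[gi]], nm)]
      if (any(is.na(idx))) next
      geom <- ring_geometry(coords, idx)
      label <- paste0(residue_code(rn), a$residue_number[rows[1]],
                      if (length(tpls) > 1) paste0(".ring", gi) else "")
      if (geom$rms_out > 0.3) {
        warning("ring ", label, " is non-planar (RMS out-of-plane ",
                round(geom$rms_out, 2), " A); skipped", call. = FALSE)
        next
      }
      rings[[label]] <- geom
    }
  }
  out <- list()
  nm <- names(rings)
  if (length(rings) >= 2) {
    for (i in seq_len(length(rings) - 1)) for (j in (i + 1):length(rings)) {
      d <- sqrt(sum((rings[[i]]$center - rings[[j]]$center)^2))
      if (d > max_dist) next
      cosang <- abs(sum(rings[[i]]$normal * rings[[j]]$normal))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi  # folded to [0, 90]
      cls <- if (ang <= 30) "parallel" else if (ang >= 60) "t_shaped" else NA
      if (is.na(cls)) next
      out[[length(out) + 1]] <- data.frame(
        kind = "pi_pi", key = paste0(nm[i], "~", nm[j]), distance = d,
        angle = ang, geometry = cls, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(kind = character(0), key = character(0),
                      distance = numeric(0), angle = numeric(0),
                      geometry = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Detect metal coordination contacts in one frame
#'
#' Every O or N atom within the cutoff of a metal atom (matched by
#' element) is recorded.  If the metal is absent an empty table is
#' returned with a warning.
#'
#' @param coords `N x 3` frame coordinates
#' @param topology matching [topology()]
#' @param metal element symbol (default `"MG"`)
#' @param cutoff coordination cutoff (A)
#' @return data.frame of interaction records
#' @export
detect_metal_coordination <- function(coords, topology, metal = "MG",
                                      cutoff = 2.6) {
  coords <- as.matrix(coords)
  a <- topology$atoms
  metals <- which(toupper(a$element) == toupper(metal))
  if (length(metals) == 0) {
    warning("no ", metal, " atom in the topology")
    return(data.frame(kind = character(0), key = character(0),
                      distance = numeric(0), angle = numeric(0),
                      stringsAsFactors = FALSE))
  }
  partners <- which(toupper(a$element) %in% c("O", "N"))
  out <- list()
  for (mi in metals) {
    for (pi in partners) {
      d <- sqrt(sum((coords[mi, ] - coords[pi, ])^2))
      if (d <= cutoff) {
        out[[length(out) + 1]] <- data.frame(
          kind = "metal",
          key = paste0(toupper(metal), a$residue_number[mi], "..",
                       residue_code(a$residue_name[pi]),
                       a$residue_number[pi], "-", trimws(a$name[pi])),
          distance = d, angle = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(kind = character(0), key = character(0),
                      distance = numeric(0), angle = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Interaction occupancy over a trajectory
#'
#' Runs a frame-local detector over every frame and reports, per unique
#' interaction key, the percentage of frames in which it is present.
#' Interactions absent from all frames do not appear (there is no
#' universe of candidate keys to zero-fill).
#'
#' @param traj a [trajectory()]
#' @param kind `"hbond"`, `"salt_bridge"`, `"pi_pi"` or `"metal"`
#' @param ... passed to the detector (criteria, cutoffs, explicit
#'   donors/acceptors, `heavy_fallback`)
#' @return data.frame with columns `key`, `kind`, `n_present`,
#'   `occupancy` (percent), sorted by decreasing occupancy
#' @export
occupancy <- function(traj, kind = c("hbond", "salt_bridge", "pi_pi", "metal"),
                      ...) {
  kind <- match.arg(kind)
  detector <- switch(kind, hbond = detect_hbonds,
                     salt_bridge = detect_salt_bridges,
                     pi_pi = detect_pi_pi, metal = detect_metal_coordination)
  nf <- n_frames(traj)
  tally <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    rec <- detector(frame_coords(traj, f), traj$topology, ...)
    for (k in unique(rec$key)) {
      tally[[k]] <- (if (is.null(tally[[k]])) 0L else tally[[k]]) + 1L
    }
  }
  keys <- ls(tally)
  if (length(keys) == 0) {
    return(data.frame(key = character(0), kind = character(0),
                      n_present = integer(0), occupancy = numeric(0),
                      stringsAsFactors = FALSE))
  }
  n_present <- vapply(keys, function(k) tally[[k]], integer(1))
  out <- data.frame(key = keys, kind = kind, n_present = n_present,
                    occupancy = 100 * n_present / nf,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$occupancy, out$key), ]
  rownames(out) <- NULL
  out
}

#' Difference between two interaction networks
#'
#' Set differences on interaction keys, order-stable with respect to the
#' inputs.
#'
#' @param state_a,state_b interaction record data.frames (or character
#'   vectors of keys)
#' @return list with `appeared` (in b only), `disappeared` (in a only),
#'   `shared`
#' @export
network_diff <- function(state_a, state_b) {
  ka <- unique(if (is.data.frame(state_a)) state_a$key else as.character(state_a))
  kb <- unique(if (is.data.frame(state_b)) state_b$key else as.character(state_b))
  list(appeared = kb[!kb %in% ka],
       disappeared = ka[!ka %in% kb],
       shared = ka[ka %in% kb])
}
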