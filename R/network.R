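#' @useDynLib willisim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Named circle-of-Willis segments every shipped network must contain:
# the model assumes a complete CoW (communicating arteries present).
COW_REQUIRED <- c("L_ICA", "R_ICA", "L_ACA_A1", "R_ACA_A1",
                  "L_ACA_A2", "R_ACA_A2", "L_MCA", "R_MCA",
                  "L_PCA_P1", "R_PCA_P1", "L_PCA_P2", "R_PCA_P2",
                  "Acom", "L_Pcom", "R_Pcom", "BA", "L_VA", "R_VA",
                  "L_ECA", "R_ECA", "L_CCA", "R_CCA")

#' Load an arterial network fixture
#'
#' Reads the JSON network dialect documented in the package README:
#' per-segment records (geometry, wall properties), junction records
#' (node id + attached segment ends), terminal records (RCR Windkessel
#' or autoregulating bed), the inflow boundary, and blood properties.
#' The network is schema-validated on load; see [validate_network()].
#'
#' @param path JSON fixture file
#' @return object of class `arterial_network`
#' @export
load_network <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  segs <- as.data.frame(raw$segments)
  need <- c("id", "name", "length_cm", "r_prox_cm", "r_dist_cm",
            "h_cm", "E_dyn_cm2")
  miss <- setdiff(need, names(segs))
  if (length(miss)) stop("segment records missing fields: ",
                         paste(miss, collapse = ", "))
  if (is.null(segs$alpha)) segs$alpha <- 1.0
  blood <- list(rho = raw$blood$rho, mu = raw$blood$mu)
  # friction coefficient for the momentum sink -K_R Q/A; default is the
  # polynomial velocity-profile closure K_R = 22 pi mu / rho
  if (is.null(segs$K_R)) segs$K_R <- 22 * pi * blood$mu / blood$rho
  juncs <- lapply(seq_along(raw$junctions$node_id), function(i) {
    att <- raw$junctions$attached[[i]]
    if (is.null(dim(att))) att <- matrix(att, ncol = 2)
    list(node_id = raw$junctions$node_id[i],
         attached = lapply(seq_len(nrow(att)),
                           function(j) list(segment = att[j, 1],
                                            end = att[j, 2])))
  })
  terms <- as.data.frame(raw$terminals)
  if (is.null(terms$q0_ml_min)) terms$q0_ml_min <- NA_real_
  sten <- if (length(raw$stenoses$segment)) {
    as.data.frame(raw$stenoses)
  } else {
    data.frame(segment = character(), start_offset_mm = numeric(),
               length_mm = numeric(), ratio = numeric())
  }
  clamps <- if (length(raw$clamps$segment)) {
    as.data.frame(raw$clamps)
  } else {
    data.frame(segment = character(), position_mm = numeric())
  }
  net <- structure(list(
    fixture_version = raw$fixture_version,
    reference_age = raw$reference_age,
    blood = blood,
    inflow = raw$inflow,
    segments = segs,
    junctions = juncs,
    terminals = terms,
    stenoses = sten,
    clamps = clamps
  ), class = "arterial_network")
  validate_network(net)
  net
}

#' Write an arterial network to the JSON fixture dialect
#'
#' Inverse of [load_network()]; round-trips all fields.
#'
#' @param net an `arterial_network`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_network <- function(net, path) {
  juncs <- data.frame(node_id = vapply(net$junctions, `[[`, "", "node_id"))
  juncs$attached <- lapply(net$junctions, function(j) {
    m <- do.call(rbind, lapply(j$attached, function(a) c(a$segment, a$end)))
    matrix(m, ncol = 2)
  })
  out <- list(fixture_version = net$fixture_version,
              reference_age = net$reference_age,
              blood = net$blood,
              inflow = net$inflow,
              segments = net$segments,
              junctions = juncs,
              terminals = net$terminals,
              stenoses = net$stenoses,
              clamps = net$clamps)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

# enumerate every (segment, end) attachment across junctions, terminals
# and the inflow boundary
.attachments <- function(net) {
  at <- list()
  for (j in net$junctions) {
    for (a in j$attached) {
      at[[length(at) + 1L]] <- c(j$node_id, a$segment, a$end)
    }
  }
  for (i in seq_len(nrow(net$terminals))) {
    at[[length(at) + 1L]] <- c(paste0("term:", net$terminals$segment[i]),
                               net$terminals$segment[i], "distal")
  }
  at[[length(at) + 1L]] <- c("inflow", net$inflow$segment, "proximal")
  do.call(rbind, at)
}

#' Validate an arterial network
#'
#' Checks segment geometry positivity, unique ids, junction arity
#' (2--4 attached ends), that every segment end is attached to exactly
#' one junction, terminal or the inflow boundary, global connectivity,
#' positive blood properties, and that the cerebral subtree contains
#' the full set of named circle-of-Willis segments (the model assumes
#' a complete CoW).  Errors name the offending record.
#'
#' @param net an `arterial_network`
#' @return `net`, invisibly, if valid; otherwise an error
#' @export
validate_network <- function(net) {
  segs <- net$segments
  if (anyDuplicated(segs$id)) {
    stop("duplicate segment id: ",
         paste(unique(segs$id[duplicated(segs$id)]), collapse = ", "))
  }
  bad <- segs$id[segs$length_cm <= 0 | segs$r_prox_cm <= 0 |
                   segs$r_dist_cm <= 0 | segs$h_cm <= 0 |
                   segs$E_dyn_cm2 <= 0 | segs$alpha < 1]
  if (length(bad)) stop("non-positive geometry/stiffness (or alpha < 1) in ",
                        "segment: ", paste(bad, collapse = ", "))
  if (!(net$blood$rho > 0 && net$blood$mu > 0)) {
    stop("blood density and viscosity must be positive")
  }
  for (j in net$junctions) {
    n <- length(j$attached)
    if (n < 2 || n > 4) {
      stop("junction ", j$node_id, " has ", n,
           " attachments (must be 2-4)")
    }
    key <- vapply(j$attached, function(a) paste(a$segment, a$end), "")
    if (anyDuplicated(key)) {
      stop("junction ", j$node_id, " attaches the same segment end twice")
    }
  }
  at <- .attachments(net)
  unknown <- setdiff(at[, 2], segs$id)
  if (length(unknown)) stop("attachment references unknown segment: ",
                            paste(unique(unknown), collapse = ", "))
  key <- paste(at[, 2], at[, 3])
  dup <- key[duplicated(key)]
  if (length(dup)) stop("segment end attached more than once: ",
                        paste(unique(dup), collapse = "; "))
  all_ends <- c(paste(segs$id, "proximal"), paste(segs$id, "distal"))
  dangling <- setdiff(all_ends, key)
  if (length(dangling)) stop("dangling segment end: ",
                             paste(dangling, collapse = "; "))
  if (sum(at[, 1] == "inflow") != 1) stop("exactly one inflow boundary required")
  # connectivity: segments as nodes, junctions as edges
  reach <- reachable_segments(net)
  if (!setequal(reach, segs$id)) {
    stop("network not connected; unreachable segment: ",
         paste(setdiff(segs$id, reach), collapse = ", "))
  }
  miss <- setdiff(COW_REQUIRED, segs$id)
  if (length(miss)) {
    stop("incomplete circle of Willis: missing segment ",
         paste(miss, collapse = ", "),
         " (the model assumes a complete CoW)")
  }
  invisible(net)
}

#' Segments reachable from the inflow boundary
#'
#' Breadth-first traversal over junction connectivity, treating clamps
#' and fully occluded (ratio = 1) stenoses as cuts when
#' `cut_interventions = TRUE`.  Used by validation and by tests of the
#' clamp semantics.
#'
#' @param net an `arterial_network`
#' @param cut_interventions treat clamps/occlusions as disconnections
#' @return character vector of reachable segment ids (a clamped
#'   segment is reachable if either of its halves is)
#' @export
reachable_segments <- function(net, cut_interventions = FALSE) {
  cut <- character()
  if (cut_interventions) {
    cut <- union(net$clamps$segment,
                 net$stenoses$segment[net$stenoses$ratio >= 1])
  }
  # adjacency between segments through junctions; a cut segment does
  # not transmit between its own two ends
  adj <- list()
  for (j in net$junctions) {
    ids <- vapply(j$attached, `[[`, "", "segment")
    for (s in ids) adj[[s]] <- union(adj[[s]], setdiff(ids, s))
  }
  root <- net$inflow$segment
  seen <- character()
  queue <- root
  while (length(queue)) {
    s <- queue[1]; queue <- queue[-1]
    if (s %in% seen) next
    seen <- c(seen, s)
    if (s %in% cut) next   # wave stops inside a cut segment
    queue <- c(queue, setdiff(adj[[s]], seen))
  }
  seen
}

.find_segment <- function(net, id) {
  i <- match(id, net$segments$id)
  if (is.na(i)) stop("unknown segment id: ", id)
  as.list(net$segments[i, , drop = FALSE])
}

#' Install a stenosis on a segment
#'
#' Records a lumped stenosis interface on the host segment (the solver
#' splits the segment at the stenosis site and couples the halves
#' through the trans-stenotic pressure-loss element).  A ratio of 0
#' leaves the network hemodynamically identical to the input (no
#' element is installed); a ratio of 1 marks the site as fully
#' occluded, realised as a zero-flow interface.  Pure: the input
#' network is not modified.
#'
#' @param net an `arterial_network`
#' @param spec list with `segment`, `start_offset_mm`, `length_mm`,
#'   `ratio` in `[0, 1]` (diameter-based lumen reduction)
#' @return a new `arterial_network` carrying the stenosis
#' @export
apply_stenosis <- function(net, spec) {
  seg <- .find_segment(net, spec$segment)
  stopifnot(spec$start_offset_mm >= 0, spec$length_mm > 0,
            spec$ratio >= 0, spec$ratio <= 1)
  if (spec$start_offset_mm + spec$length_mm > seg$length_cm * 10 + 1e-9) {
    stop("stenosis extends beyond segment ", spec$segment,
         " (length ", seg$length_cm * 10, " mm)")
  }
  if (spec$ratio == 0) return(net)
  net$stenoses <- rbind(net$stenoses,
                        data.frame(segment = spec$segment,
                                   start_offset_mm = spec$start_offset_mm,
                                   length_mm = spec$length_mm,
                                   ratio = spec$ratio))
  net
}

#' Install a clamp (total flow blockade) on a segment
#'
#' Records a zero-flow internal boundary at the given position.  Flow
#' across the clamp is identically zero; both sides remain part of the
#' solved domain, so the distal stump pressure is observable.  Pure:
#' the input network is not modified.
#'
#' @param net an `arterial_network`
#' @param spec list with `segment` and `position_mm` from the proximal
#'   end
#' @return a new `arterial_network` carrying the clamp
#' @export
apply_clamp <- function(net, spec) {
  seg <- .find_segment(net, spec$segment)
  if (spec$position_mm <= 0 || spec$position_mm >= seg$length_cm * 10) {
    stop("clamp position must lie strictly inside segment ", spec$segment)
  }
  at <- .attachments(net)
  prox <- at[at[, 2] == spec$segment & at[, 3] == "proximal", 1]
  if (startsWith(prox, "term:")) {
    stop("cannot clamp terminal-only stub segment ", spec$segment)
  }
  net$clamps <- rbind(net$clamps,
                      data.frame(segment = spec$segment,
                                 position_mm = spec$position_mm))
  net
}
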