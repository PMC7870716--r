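#' Innervation table of the head-direction circuit
#'
#' Builds the arbor table of the four neuron classes innervating the
#' protocerebral bridge (PB, nine glomeruli per hemisphere) and the ellipsoid
#' body (EB, eight tiles): one row per synaptic terminal with its volume and
#' polarity.
#'
#' The encoded projection patterns are:
#' \describe{
#'   \item{E-PG}{18 neurons (`E-PG_1..9` in each hemisphere): input in one EB
#'     tile, output in the equally numbered PB glomerulus of their
#'     hemisphere. `E-PG_9` takes input from tile T1, closing the ring.}
#'   \item{P-EG}{18 neurons: input in one PB glomerulus, output in the
#'     equally numbered EB tile; `P-EG_9` outputs to T1.}
#'   \item{P-EN}{16 neurons: `P-EN_1..8` in the left hemisphere projecting
#'     from glomerulus Gk to tile T(k+1), `P-EN_2..9` in the right hemisphere
#'     projecting from Gk to T(k-1) (tiles mod 8). The two middlemost
#'     glomeruli (left G9, right G1) are not innervated.}
#'   \item{Delta7}{8 PB-intrinsic neurons whose output domains sit at linear
#'     PB positions `n, n+8, n+16` (positions L1..L9 then R1..R9), i.e.
#'     separated by seven glomeruli, with input terminals in all remaining
#'     glomeruli.}
#' }
#'
#' @return A data.frame of class `cx_arbors` with columns `neuron_id`,
#'   `class` (`E-PG`, `P-EG`, `P-EN`, `Delta7`), `volume_kind`
#'   (`PB-glomerulus` or `EB-tile`), `hemisphere` (`L`, `R` or `none`),
#'   `index` (glomerulus 1-9 or tile 1-8) and `polarity` (`input`/`output`).
#' @examples
#' arb <- cx_arbors()
#' subset(arb, neuron_id == "P-EN_1_L")
#' @export
cx_arbors <- function() {
  rows <- list()
  add <- function(id, cls, kind, hemi, index, pol) {
    rows[[length(rows) + 1L]] <<- data.frame(
      neuron_id = id, class = cls, volume_kind = kind, hemisphere = hemi,
      index = as.integer(index), polarity = pol, stringsAsFactors = FALSE)
  }
  tile_of <- function(k) ((k - 1L) %% 8L) + 1L # G9 -> T1 wrap

  for (h in c("L", "R")) {
    for (k in 1:9) {
      add(sprintf("E-PG_%d_%s", k, h), "E-PG", "EB-tile", "none", tile_of(k), "input")
      add(sprintf("E-PG_%d_%s", k, h), "E-PG", "PB-glomerulus", h, k, "output")
      add(sprintf("P-EG_%d_%s", k, h), "P-EG", "PB-glomerulus", h, k, "input")
      add(sprintf("P-EG_%d_%s", k, h), "P-EG", "EB-tile", "none", tile_of(k), "output")
    }
  }
  for (k in 1:8) { # left P-EN: Gk -> T(k+1)
    add(sprintf("P-EN_%d_L", k), "P-EN", "PB-glomerulus", "L", k, "input")
    add(sprintf("P-EN_%d_L", k), "P-EN", "EB-tile", "none", tile_of(k + 1L), "output")
  }
  for (k in 2:9) { # right P-EN: Gk -> T(k-1)
    add(sprintf("P-EN_%d_R", k), "P-EN", "PB-glomerulus", "R", k, "input")
    add(sprintf("P-EN_%d_R", k), "P-EN", "EB-tile", "none", tile_of(k - 1L + 8L), "output")
  }
  # Delta7: linear PB positions 1..18 = L1..L9, R1..R9
  pos_hemi <- function(p) ifelse(p <= 9L, "L", "R")
  pos_idx <- function(p) ifelse(p <= 9L, p, p - 9L)
  for (n in 1:8) {
    id <- sprintf("Delta7_%d", n)
    out_pos <- c(n, n + 8L, n + 16L)
    out_pos <- out_pos[out_pos <= 18L]
    for (p in out_pos)
      add(id, "Delta7", "PB-glomerulus", pos_hemi(p), pos_idx(p), "output")
    for (p in setdiff(1:18, out_pos))
      add(id, "Delta7", "PB-glomerulus", pos_hemi(p), pos_idx(p), "input")
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cx_arbors", "data.frame")
  out
}

#' Read or write an arbor table as CSV
#'
#' @param arbors A `cx_arbors` data.frame (see [cx_arbors()]).
#' @param file Path to a CSV file with columns `neuron_id`, `class`,
#'   `volume_kind`, `hemisphere`, `index`, `polarity`.
#' @return `write_arbors_csv` returns `file` invisibly; `read_arbors_csv`
#'   returns a `cx_arbors` data.frame.
#' @export
write_arbors_csv <- function(arbors, file) {
  utils::write.csv(as.data.frame(arbors), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_arbors_csv
#' @export
read_arbors_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("neuron_id", "class", "volume_kind", "hemisphere", "index", "polarity")
  if (!all(need %in% names(df))) stop("read_arbors_csv: missing columns")
  df <- df[, need]
  df$index <- as.integer(df$index)
  class(df) <- c("cx_arbors", "data.frame")
  validate_arbors(df)
  df
}

validate_arbors <- function(arbors) {
  stopifnot(is.data.frame(arbors), nrow(arbors) > 0)
  ok_g <- arbors$volume_kind != "PB-glomerulus" |
    (arbors$index >= 1 & arbors$index <= 9 & arbors$hemisphere %in% c("L", "R"))
  ok_t <- arbors$volume_kind != "EB-tile" |
    (arbors$index >= 1 & arbors$index <= 8 & arbors$hemisphere == "none")
  if (!all(ok_g & ok_t)) stop("invalid volume in arbor table")
  pol <- split(arbors$polarity, arbors$neuron_id)
  bad <- names(pol)[!vapply(pol, function(p) all(c("input", "output") %in% p), logical(1))]
  if (length(bad))
    stop("arbors without both input and output terminals: ",
         paste(bad, collapse = ", "))
  invisible(arbors)
}

vol_key <- function(kind, hemi, index) paste(kind, hemi, index, sep = ":")

#' Infer synapses from overlapping terminals
#'
#' Builds the raw directed synapse graph: a multi-edge `pre -> post` exists
#' for every volume in which `pre` has an output terminal and `post` an input
#' terminal. Edges are inhibitory (sign -1) when the presynaptic class is
#' Delta7 and excitatory (+1) otherwise.
#'
#' @param arbors A `cx_arbors` data.frame.
#' @return An object of class `cx_synapse_graph`: a list with `neurons`
#'   (data.frame `neuron_id`, `class`), `edges` (data.frame `pre`, `post`,
#'   `volume_kind`, `hemisphere`, `index`, `sign`) and the `arbors` table.
#' @examples
#' g <- infer_synapses(cx_arbors())
#' nrow(g$edges)
#' @export
infer_synapses <- function(arbors) {
  validate_arbors(arbors)
  arbors$vol <- vol_key(arbors$volume_kind, arbors$hemisphere, arbors$index)
  outs <- arbors[arbors$polarity == "output", ]
  ins <- arbors[arbors$polarity == "input", ]
  edges <- merge(
    outs[, c("neuron_id", "class", "volume_kind", "hemisphere", "index", "vol")],
    ins[, c("neuron_id", "vol")],
    by = "vol", suffixes = c("_pre", "_post"))
  edges <- edges[edges$neuron_id_pre != edges$neuron_id_post, ]
  edges <- data.frame(
    pre = edges$neuron_id_pre, post = edges$neuron_id_post,
    volume_kind = edges$volume_kind, hemisphere = edges$hemisphere,
    index = edges$index,
    sign = ifelse(edges$class == "Delta7", -1L, 1L),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$pre, edges$post, edges$hemisphere, edges$index), ]
  rownames(edges) <- NULL
  neurons <- unique(arbors[, c("neuron_id", "class")])
  neurons <- neurons[order(neurons$neuron_id), ]
  rownames(neurons) <- NULL
  structure(list(neurons = neurons, edges = edges, arbors = arbors),
            class = "cx_synapse_graph")
}

#' @export
print.cx_synapse_graph <- function(x, ...) {
  cat(sprintf("Raw synapse graph: %d neurons, %d directed multi-edges\n",
              nrow(x$neurons), nrow(x$edges)))
  print(table(x$neurons$class))
  invisible(x)
}

# Signal-class signature of each neuron: (class, sorted set of in-volume
# signal ids). Two neurons with the same signature carry the same signal.
neuron_signal_sig <- function(arbors, vol_class) {
  ins <- arbors[arbors$polarity == "input", ]
  sig_in <- tapply(vol_class[ins$vol], ins$neuron_id,
                   function(v) paste(sort(unique(v)), collapse = ","))
  cls <- tapply(arbors$class, arbors$neuron_id, function(x) x[[1]])
  paste(cls[names(sig_in)], sig_in, sep = "|")
}

#' Reduce the raw synapse graph to the effective circuit
#'
#' Iteratively merges duplicate neurons into effective functional units and
#' collapses parallel edges, reproducing the reduction of the mirrored
#' left/right PB innervation to an eight-fold ring. Two same-class neurons
#' merge when they receive the same signal (identical sets of input-volume
#' signal classes) and write to the same signal volumes; P-EN laterality is
#' preserved so each octant keeps its left/right pair. Volume signal classes
#' start from the functional identification of equally numbered PB glomeruli
#' across hemispheres (the observed twin activity bumps) and are themselves
#' refined each iteration: two volumes are identified when the signals
#' written into them coincide, which is what closes the ring between
#' glomeruli G1 and G9.
#'
#' @param graph A `cx_synapse_graph` from [infer_synapses()], or an existing
#'   `cx_circuit` (in which case the reduction is re-applied to the unit
#'   graph; a fully reduced circuit is returned unchanged).
#' @param max_iter Iteration bound; exceeding it raises an error.
#' @return An object of class `cx_circuit`: a list with `units` (data.frame
#'   `unit`, `class`, `octant`, `laterality`), `edges` (data.frame `pre`,
#'   `post`, `sign`) and `members` (named list mapping unit to merged
#'   neuron ids).
#' @examples
#' cir <- reduce_circuit(infer_synapses(cx_arbors()))
#' table(cir$units$class)
#' @export
reduce_circuit <- function(graph, max_iter = 50L) {
  UseMethod("reduce_circuit")
}

#' @export
reduce_circuit.cx_synapse_graph <- function(graph, max_iter = 50L) {
  arbors <- graph$arbors
  if (is.null(arbors$vol))
    arbors$vol <- vol_key(arbors$volume_kind, arbors$hemisphere, arbors$index)
  vols <- unique(arbors[, c("volume_kind", "hemisphere", "index", "vol")])

  # Base volume signal classes: PB glomeruli identified across hemispheres.
  vol_class <- ifelse(vols$volume_kind == "PB-glomerulus",
                      paste("PB", vols$index, sep = ":"), vols$vol)
  names(vol_class) <- vols$vol

  lat <- ifelse(arbors$class == "P-EN", arbors$hemisphere, "")
  lat_of <- tapply(lat, arbors$neuron_id, function(x) setdiff(x, "none")[1])
  lat_of[is.na(lat_of)] <- ""
  cls_of <- tapply(arbors$class, arbors$neuron_id, function(x) x[[1]])
  ins <- arbors[arbors$polarity == "input", ]
  outs <- arbors[arbors$polarity == "output", ]

  unit_of <- NULL
  for (it in seq_len(max_iter)) {
    # (1) merge neurons: same class & laterality, same in/out signal sets
    in_sig <- tapply(vol_class[ins$vol], ins$neuron_id,
                     function(v) paste(sort(unique(v)), collapse = ","))
    out_sig <- tapply(vol_class[outs$vol], outs$neuron_id,
                      function(v) paste(sort(unique(v)), collapse = ","))
    ids <- names(cls_of)
    key <- paste(cls_of[ids], lat_of[ids], in_sig[ids], out_sig[ids], sep = "|")
    new_unit <- as.integer(factor(key, levels = unique(key)))
    names(new_unit) <- ids

    # (2) identify volumes whose writers carry identical signals
    nsig <- paste(cls_of, in_sig[names(cls_of)], sep = "|")
    names(nsig) <- names(cls_of)
    writer_sig <- tapply(nsig[outs$neuron_id], vol_class[outs$vol],
                         function(v) paste(sort(unique(v)), collapse = ";"))
    vc_key <- paste(sub(":.*", "", names(writer_sig)), writer_sig)
    remap <- stats::setNames(vc_key, names(writer_sig))
    new_vol_class <- ifelse(vol_class %in% names(remap),
                            remap[vol_class], vol_class)
    names(new_vol_class) <- names(vol_class)

    converged <- !is.null(unit_of) && identical(unname(new_unit), unname(unit_of)) &&
      identical(unname(as.integer(factor(new_vol_class, levels = unique(new_vol_class)))),
                unname(as.integer(factor(vol_class, levels = unique(vol_class)))))
    unit_of <- new_unit
    vol_class <- new_vol_class
    if (converged) break
    if (it == max_iter) stop("reduce_circuit: no convergence after ", max_iter,
                             " iterations")
  }

  build_circuit(unit_of, cls_of, lat_of, graph$edges, arbors)
}

#' @export
reduce_circuit.cx_circuit <- function(graph, max_iter = 50L) {
  # Re-apply neighborhood-based merging at unit level; a reduced circuit is a
  # fixpoint and comes back unchanged.
  units <- graph$units
  edges <- graph$edges
  part <- seq_len(nrow(units))
  names(part) <- units$unit
  for (it in seq_len(max_iter)) {
    inn <- tapply(part[edges$pre], edges$post,
                  function(v) paste(sort(unique(v)), collapse = ","))
    out <- tapply(part[edges$post], edges$pre,
                  function(v) paste(sort(unique(v)), collapse = ","))
    key <- paste(units$class, units$laterality,
                 inn[units$unit], out[units$unit], sep = "|")
    new_part <- as.integer(factor(key, levels = unique(key)))
    names(new_part) <- units$unit
    if (identical(unname(new_part), unname(part))) break
    part <- new_part
    if (it == max_iter) stop("reduce_circuit: no convergence")
  }
  if (length(unique(part)) == nrow(units)) return(graph)
  keep <- !duplicated(part)
  map <- units$unit[keep][match(part, part[keep])]
  names(map) <- units$unit
  e <- unique(data.frame(pre = unname(map[edges$pre]),
                         post = unname(map[edges$post]), sign = edges$sign))
  e <- e[e$pre != e$post, ]
  rownames(e) <- NULL
  members <- lapply(units$unit[keep], function(u) {
    sort(unique(unlist(graph$members[units$unit[map[units$unit] == u]],
                       use.names = FALSE)))
  })
  names(members) <- units$unit[keep]
  structure(list(units = units[keep, ], edges = e, members = members),
            class = "cx_circuit")
}

build_circuit <- function(unit_of, cls_of, lat_of, raw_edges, arbors) {
  ids <- names(unit_of)
  members <- split(ids, unit_of[ids])
  # octant: from the neuron numbering (Gk with 9 -> 1); Delta7 by its number
  num_of <- suppressWarnings(as.integer(sub("^[^_]+_([0-9]+).*$", "\\1", ids)))
  names(num_of) <- ids
  octant_of_neuron <- ifelse(is.na(num_of), NA_integer_,
                             ((num_of - 1L) %% 8L) + 1L)
  names(octant_of_neuron) <- ids

  unit_ids <- sort(unique(unit_of))
  info <- lapply(unit_ids, function(u) {
    m <- members[[as.character(u)]]
    cls <- unname(cls_of[m[1]])
    lat <- unname(lat_of[m[1]])
    oct <- unique(octant_of_neuron[m])
    oct <- if (length(oct) == 1 && !is.na(oct)) oct else NA_integer_
    label <- if (!is.na(oct)) {
      if (cls == "P-EN") sprintf("P-EN_%d_%s", oct, lat)
      else sprintf("%s_%d", cls, oct)
    } else paste0(cls, "_u", u)
    data.frame(unit = label, class = cls, octant = oct,
               laterality = ifelse(lat == "", "merged", lat),
               stringsAsFactors = FALSE)
  })
  units <- do.call(rbind, info)
  if (anyDuplicated(units$unit))
    units$unit <- make.unique(units$unit, sep = "_m")
  label_of <- stats::setNames(rep(units$unit, lengths(members[as.character(unit_ids)])),
                              unlist(members[as.character(unit_ids)]))
  e <- data.frame(pre = unname(label_of[raw_edges$pre]),
                  post = unname(label_of[raw_edges$post]),
                  sign = raw_edges$sign, stringsAsFactors = FALSE)
  e <- e[e$pre != e$post, ]
  e <- unique(e)
  if (anyDuplicated(e[, c("pre", "post")]))
    stop("reduce_circuit: conflicting edge signs after merging")
  e <- e[order(e$pre, e$post), ]
  rownames(e) <- NULL
  units <- units[order(match(units$class, c("E-PG", "P-EG", "P-EN", "Delta7")),
                       units$laterality, units$octant), ]
  rownames(units) <- NULL
  mem <- stats::setNames(members[as.character(unit_ids)],
                         vapply(info, function(x) x$unit, character(1)))
  structure(list(units = units, edges = e, members = mem[units$unit]),
            class = "cx_circuit")
}

#' @export
print.cx_circuit <- function(x, ...) {
  cat(sprintf("Effective circuit: %d units, %d signed edges\n",
              nrow(x$units), nrow(x$edges)))
  print(table(x$units$class, x$units$laterality))
  cat(sprintf("Radial symmetry order: %d\n", check_radial_symmetry(x)))
  invisible(x)
}

#' Synaptic weight vector of the five tied weight classes
#'
#' The free parameters of the model: one weight per synapse class, in
#' `i_psc` unit equivalents flowing to the postsynaptic neuron per action
#' potential. Excitatory weights are bounded in \[0, 100\], inhibitory
#' (Delta7 presynaptic) in \[-100, 0\].
#'
#' @param w1 E-PG to P-EN, P-EG and Delta7 (tied).
#' @param w2 P-EN to E-PG.
#' @param w3 P-EG to E-PG.
#' @param w4 Delta7 to P-EN and P-EG (tied).
#' @param w5 Delta7 to Delta7.
#' @return Named numeric vector of class `cx_weights`.
#' @examples
#' cx_weights(0.5, 0.5, 0.5, -0.5, -0.5)
#' @export
cx_weights <- function(w1 = 0.01, w2 = 0.01, w3 = 0.01, w4 = -0.01, w5 = -0.01) {
  w <- c(w1 = unname(w1), w2 = unname(w2), w3 = unname(w3),
         w4 = unname(w4), w5 = unname(w5))
  validate_weights(w)
  class(w) <- "cx_weights"
  w
}

validate_weights <- function(w) {
  stopifnot(length(w) == 5, all(is.finite(w)))
  if (any(w[1:3] < 0) || any(w[1:3] > 100))
    stop("excitatory weights w1..w3 must lie in [0, 100]")
  if (any(w[4:5] > 0) || any(w[4:5] < -100))
    stop("inhibitory weights w4, w5 must lie in [-100, 0]")
  invisible(w)
}

weight_class_map <- function() {
  # (pre class -> post class) => weight name
  c("E-PG->P-EG" = "w1", "E-PG->P-EN" = "w1", "E-PG->Delta7" = "w1",
    "P-EN->E-PG" = "w2", "P-EG->E-PG" = "w3",
    "Delta7->P-EG" = "w4", "Delta7->P-EN" = "w4", "Delta7->Delta7" = "w5")
}

#' Signed weighted connectivity matrix of the effective circuit
#'
#' Maps every effective edge to its tied weight class and returns the
#' `N x N` matrix `M` with `M[j, i]` the signed weight of the edge from unit
#' `j` to unit `i`, zero otherwise. Unit ordering is class-major
#' (E-PG, P-EG, P-EN left, P-EN right, Delta7), octant-minor, and is stable;
#' labels are carried in `dimnames`.
#'
#' @param circuit A `cx_circuit`.
#' @param weights A [cx_weights()] vector.
#' @return A numeric matrix with unit labels as dimnames and the unit table
#'   as attribute `units`.
#' @examples
#' cir <- reduce_circuit(infer_synapses(cx_arbors()))
#' M <- connectivity_matrix(cir, cx_weights(1, 1, 1, -1, -1))
#' sum(M != 0) # one entry per effective edge
#' @export
connectivity_matrix <- function(circuit, weights = cx_weights()) {
  validate_weights(weights)
  units <- circuit$units
  lab <- units$unit
  cls <- stats::setNames(units$class, lab)
  n <- length(lab)
  M <- matrix(0, n, n, dimnames = list(lab, lab))
  ek <- paste0(cls[circuit$edges$pre], "->", cls[circuit$edges$post])
  wmap <- weight_class_map()
  unknown <- setdiff(unique(ek), names(wmap))
  if (length(unknown))
    stop("no weight parameter mapped for edge class(es): ",
         paste(unknown, collapse = ", "))
  wname <- wmap[ek]
  val <- unclass(weights)[wname]
  bad_sign <- (circuit$edges$sign > 0 & val < 0) | (circuit$edges$sign < 0 & val > 0)
  if (any(bad_sign)) stop("weight sign inconsistent with edge sign")
  M[cbind(circuit$edges$pre, circuit$edges$post)] <- val
  attr(M, "units") <- units
  M
}

#' Order of rotational symmetry of the effective circuit
#'
#' Returns the largest `k` dividing 8 such that rotating every unit's octant
#' by `8/k` (mod 8) maps the signed edge set onto itself. The circuit
#' derived from the fly anatomy has order 8.
#'
#' @param circuit A `cx_circuit`.
#' @return Integer: 8, 4, 2 or 1.
#' @export
check_radial_symmetry <- function(circuit) {
  units <- circuit$units
  if (any(is.na(units$octant))) return(1L)
  ekey <- function(e) paste(e$pre, e$post, e$sign)
  base <- sort(ekey(circuit$edges))
  rot_label <- function(lab, r) {
    i <- match(lab, units$unit)
    oct2 <- ((units$octant[i] - 1L + r) %% 8L) + 1L
    j <- match(paste(units$class[i], oct2, units$laterality[i]),
               paste(units$class, units$octant, units$laterality))
    units$unit[j]
  }
  for (k in c(8L, 4L, 2L)) {
    r <- 8L %/% k
    e2 <- data.frame(pre = rot_label(circuit$edges$pre, r),
                     post = rot_label(circuit$edges$post, r),
                     sign = circuit$edges$sign)
    if (!anyNA(e2$pre) && !anyNA(e2$post) && identical(sort(ekey(e2)), base))
      return(k)
  }
  1L
}

#' Convert an effective circuit to an igraph object
#'
#' Nodes carry `class`, `octant` and `laterality` attributes; edges carry
#' `sign` and (if `weights` given) `weight`.
#'
#' @param circuit A `cx_circuit`.
#' @param weights Optional [cx_weights()] vector.
#' @return An [igraph::graph] object.
#' @export
circuit_igraph <- function(circuit, weights = NULL) {
  g <- igraph::graph_from_data_frame(
    circuit$edges, directed = TRUE,
    vertices = data.frame(name = circuit$units$unit,
                          class = circuit$units$class,
                          octant = circuit$units$octant,
                          laterality = circuit$units$laterality))
  if (!is.null(weights)) {
    M <- connectivity_matrix(circuit, weights)
    el <- igraph::as_edgelist(g)
    igraph::E(g)$weight <- M[el]
  }
  g
}

#' Export the effective circuit as GraphML or DOT
#'
#' @param circuit A `cx_circuit`.
#' @param file Output path.
#' @param weights Optional [cx_weights()]; adds a `weight` edge attribute.
#' @return `file`, invisibly.
#' @export
write_circuit_graphml <- function(circuit, file, weights = NULL) {
  igraph::write_graph(circuit_igraph(circuit, weights), file, format = "graphml")
  invisible(file)
}

#' @rdname write_circuit_graphml
#' @export
write_circuit_dot <- function(circuit, file, weights = NULL) {
  igraph::write_graph(circuit_igraph(circuit, weights), file, format = "dot")
  invisible(file)
}

#' Export the connectivity matrix as CSV with unit labels
#'
#' @param M Matrix from [connectivity_matrix()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_matrix_csv <- function(M, file) {
  utils::write.csv(as.data.frame(M), file, row.names = TRUE)
  invisible(file)
}
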