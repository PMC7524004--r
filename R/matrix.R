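# Structured random connectivity generation: Table-style connection
# probabilities, matrix sampling, collateral completion, focal + surrounding
# composition, and a plain-text serialization format.

#' Default connection probability table
#'
#' Probabilities of a nonzero directed coupling for every allowed
#' (target population, source population) pair, separately for focal and
#' surrounding target regions. Pairs absent from the table never receive a
#' direct edge (they can still arise as collaterals). Focal probabilities are
#' four times the surrounding ones; the trigeminal input projects only onto
#' focal TC nodes.
#'
#' @return a data frame with columns `target`, `source`, `focal`,
#'   `surrounding`.
#' @export
coupling_probabilities <- function() {
  data.frame(
    target = c("PY", "PY", "PY", "IN", "IN", "IN",
               "TC", "TC", "TC", "RE", "RE", "RE"),
    source = c("PY", "IN", "TC", "PY", "IN", "TC",
               "PY", "RE", "NT", "PY", "TC", "RE"),
    focal = c(0.036, 0.126, 0.045, 0.036, 0.126, 0.045,
              0.054, 0.0225, 0.18, 0.054, 0.045, 0.0225),
    surrounding = c(0.009, 0.0315, 0.0225, 0.009, 0.0315, 0.0225,
                    0.0135, 0.01125, 0, 0.0135, 0.0225, 0.01125),
    stringsAsFactors = FALSE
  )
}

# probability lookup; returns 0 for pairs absent from the table
lookup_probability <- function(probs, target_pop, source_pop, target_region) {
  row <- probs$target == target_pop & probs$source == source_pop
  if (!any(row)) return(0)
  col <- if (target_region == "focal") "focal" else "surrounding"
  p <- probs[[col]][which(row)[1L]]
  if (is.na(p) || p < 0 || p > 1)
    stop(sprintf("invalid probability for %s <- %s (%s): %s",
                 target_pop, source_pop, target_region, p))
  p
}

validate_probabilities <- function(probs) {
  need <- c("target", "source", "focal", "surrounding")
  if (!all(need %in% names(probs)))
    stop("probability table needs columns target, source, focal, surrounding")
  bad_pop <- setdiff(unique(c(probs$target, probs$source)), POPULATIONS)
  if (length(bad_pop))
    stop("unknown population(s) in probability table: ",
         paste(bad_pop, collapse = ", "))
  if (any(probs$target == "NT" &
          (probs$focal > 0 | probs$surrounding > 0), na.rm = TRUE))
    stop("NT nodes are a pure external input and cannot receive couplings")
  vals <- c(probs$focal, probs$surrounding)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("probabilities must lie in [0, 1]")
  invisible(probs)
}

new_swd_matrix <- function(C, layout, tau_steps, w_exc, w_inh, seed = NA) {
  structure(
    list(C = C, layout = layout, tau_steps = as.integer(tau_steps),
         w_exc = w_exc, w_inh = w_inh, seed = seed),
    class = "swd_matrix"
  )
}

#' @export
print.swd_matrix <- function(x, ...) {
  cat(sprintf("<swd_matrix> %d nodes, %d edges, tau = %d steps\n",
              nrow(x$C), length(x$C@x), x$tau_steps))
  invisible(x)
}

#' Sample a structured random coupling matrix
#'
#' Draws a signed sparse coupling matrix `C` in which entry `C[i, j]` couples
#' source node `j` into target node `i`. Each allowed ordered pair (i != j)
#' receives an edge independently, with the probability looked up by
#' (target population, source population, target region). The value of a
#' nonzero entry is `+w_exc` when the source population is excitatory
#' (PY, TC, NT) and `-w_inh` when it is inhibitory (IN, RE). Self-couplings
#' are never drawn.
#'
#' @param layout an [network_layout()] object.
#' @param probs probability table as from [coupling_probabilities()].
#' @param w_exc,w_inh magnitudes of excitatory and inhibitory weights
#'   (model units; defaults 0.1 and 0.1).
#' @param tau_steps coupling delay shared by all edges, in integration steps
#'   (9 to 13 in typical use).
#' @param seed integer seed; the matrix is fully reproducible from it.
#' @return an `swd_matrix`: sparse matrix `C`, `layout`, `tau_steps`,
#'   weights and `seed`.
#' @export
#' @examples
#' m <- sample_matrix(network_layout("focal"), tau_steps = 11, seed = 1)
sample_matrix <- function(layout, probs = coupling_probabilities(),
                          w_exc = 0.1, w_inh = 0.1, tau_steps = 11L,
                          seed = 1L) {
  stopifnot(inherits(layout, "swd_layout"))
  validate_probabilities(probs)
  if (tau_steps < 1L) stop("tau_steps must be a positive integer")
  n <- attr(layout, "n_total")
  with_seed(seed, {
    ii <- integer(0); jj <- integer(0); ww <- numeric(0)
    # deterministic block order: targets then sources, in layout order
    for (tr in seq_len(nrow(layout))) {
      if (layout$population[tr] == "NT") next  # NT receives nothing
      t_idx <- seq.int(layout$first[tr], layout$last[tr])
      for (sr in seq_len(nrow(layout))) {
        p <- lookup_probability(probs, layout$population[tr],
                                layout$population[sr], layout$region[tr])
        if (p == 0) next
        s_idx <- seq.int(layout$first[sr], layout$last[sr])
        hit <- which(matrix(stats::runif(length(t_idx) * length(s_idx)),
                            length(t_idx)) < p, arr.ind = TRUE)
        if (nrow(hit) == 0L) next
        ti <- t_idx[hit[, 1L]]; sj <- s_idx[hit[, 2L]]
        keep <- ti != sj
        ti <- ti[keep]; sj <- sj[keep]
        w <- ifelse(POPULATION_SIGN[layout$population[sr]] > 0, w_exc, -w_inh)
        ii <- c(ii, ti); jj <- c(jj, sj); ww <- c(ww, rep(w, length(ti)))
      }
    }
    C <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
    new_swd_matrix(C, layout, tau_steps, w_exc, w_inh, seed)
  })
}

#' Complete collateral (reciprocal) couplings
#'
#' For every nonzero coupling `C[i, j]` the reciprocal entry `C[j, i]` is
#' made nonzero. Two readings of this completion rule are provided:
#'
#' * `"dale"` (default): the new edge's magnitude comes from the weight
#'   magnitudes and its sign from the population of node `i` — the source of
#'   the collateral — so every column keeps a single sign determined by its
#'   population.
#' * `"mirror"`: the reciprocal entry is set to the same value as the forward
#'   coupling, `C[j, i] = C[i, j]`, taking "the same value" literally; this
#'   symmetrizes the sampled edges and can give a node outgoing edges of both
#'   signs.
#'
#' The operation is idempotent under both rules. By default no collateral is
#' created into NT nodes, which act as a pure external input.
#'
#' @param m an `swd_matrix`.
#' @param rule collateral completion rule, `"dale"` or `"mirror"`.
#' @param exclude_nt_targets if `TRUE` (default), edges out of NT gain no
#'   reciprocal edge back into NT.
#' @return the completed `swd_matrix`.
#' @export
apply_collaterals <- function(m, rule = c("dale", "mirror"),
                              exclude_nt_targets = TRUE) {
  stopifnot(inherits(m, "swd_matrix"))
  rule <- match.arg(rule)
  T <- as(m$C, "TsparseMatrix")
  pops <- node_populations(m$layout)
  # reciprocal of (i <- j) is (j <- i): source is i, its population sets sign
  src <- T@i + 1L
  tgt <- T@j + 1L
  fwd <- T@x
  if (exclude_nt_targets) {
    keep <- pops[tgt] != "NT"
    src <- src[keep]; tgt <- tgt[keep]; fwd <- fwd[keep]
  }
  w <- if (rule == "dale")
    ifelse(POPULATION_SIGN[pops[src]] > 0, m$w_exc, -m$w_inh)
  else fwd
  n <- nrow(m$C)
  coll <- Matrix::sparseMatrix(i = tgt, j = src, x = w, dims = c(n, n),
                               use.last.ij = TRUE)
  # keep existing entries; fill only positions that are still zero
  fill <- coll * (abs(m$C) == 0)
  m$C <- methods::as(m$C + fill, "CsparseMatrix")
  m
}

#' Compose focal and surrounding subnetworks into one network
#'
#' Places the focal matrix (with its trigeminal input block) and the
#' surrounding matrix on the diagonal of a block matrix and samples the
#' cross-region couplings with the surrounding-area probabilities. This
#' includes the "bridge" from focal PY onto surrounding PY nodes through
#' which seizures recruit the surrounding network. Both inputs must share
#' the same coupling delay.
#'
#' @param m_focal,m_surround `swd_matrix` objects built on a focal layout
#'   (with NT) and a surrounding layout.
#' @param probs probability table; cross-blocks use its `surrounding` column.
#' @param seed integer seed for the cross-block sampling.
#' @param collaterals complete reciprocal edges for the sampled cross-block
#'   couplings (default `TRUE`, matching the generation pipeline).
#' @return an `swd_matrix` on the full layout.
#' @export
compose_network <- function(m_focal, m_surround,
                            probs = coupling_probabilities(), seed = 1L,
                            collaterals = TRUE) {
  stopifnot(inherits(m_focal, "swd_matrix"), inherits(m_surround, "swd_matrix"))
  if (m_focal$tau_steps != m_surround$tau_steps)
    stop("focal and surrounding matrices must share the same tau_steps")
  validate_probabilities(probs)
  lay_f <- m_focal$layout
  lay_s <- m_surround$layout
  if (any(lay_f$region == "surrounding") || any(lay_s$region != "surrounding"))
    stop("compose_network() expects a focal(+NT) and a surrounding matrix")
  counts <- c(stats::setNames(lay_f$n, paste(lay_f$population, lay_f$region,
                                             sep = ".")),
              stats::setNames(lay_s$n, paste(lay_s$population, lay_s$region,
                                             sep = ".")))
  layout <- network_layout("full", counts = counts)
  n <- attr(layout, "n_total")

  # embed the two diagonal blocks at their positions in the full layout
  place <- function(m) {
    T <- as(m$C, "TsparseMatrix")
    key <- paste(m$layout$population, m$layout$region, sep = ".")
    full_first <- stats::setNames(layout$first,
                                  paste(layout$population, layout$region,
                                        sep = "."))
    # per-node offset: new index = full_first[block] + (old - old_first)
    map <- integer(nrow(m$C))
    for (r in seq_len(nrow(m$layout))) {
      old <- seq.int(m$layout$first[r], m$layout$last[r])
      map[old] <- full_first[[key[r]]] + seq_along(old) - 1L
    }
    list(i = map[T@i + 1L], j = map[T@j + 1L], x = T@x)
  }
  bf <- place(m_focal); bs <- place(m_surround)

  ii <- c(bf$i, bs$i); jj <- c(bf$j, bs$j); ww <- c(bf$x, bs$x)
  w_exc <- m_focal$w_exc; w_inh <- m_focal$w_inh

  cross <- with_seed(seed, {
    ci <- integer(0); cj <- integer(0); cw <- numeric(0)
    for (tr in seq_len(nrow(layout))) {
      if (layout$population[tr] == "NT") next
      for (sr in seq_len(nrow(layout))) {
        # cross-blocks only: one side focal/external, the other surrounding
        t_surr <- layout$region[tr] == "surrounding"
        s_surr <- layout$region[sr] == "surrounding"
        if (t_surr == s_surr) next
        p <- lookup_probability(probs, layout$population[tr],
                                layout$population[sr], "surrounding")
        if (p == 0) next
        t_idx <- seq.int(layout$first[tr], layout$last[tr])
        s_idx <- seq.int(layout$first[sr], layout$last[sr])
        hit <- which(matrix(stats::runif(length(t_idx) * length(s_idx)),
                            length(t_idx)) < p, arr.ind = TRUE)
        if (nrow(hit) == 0L) next
        w <- ifelse(POPULATION_SIGN[layout$population[sr]] > 0, w_exc, -w_inh)
        ci <- c(ci, t_idx[hit[, 1L]]); cj <- c(cj, s_idx[hit[, 2L]])
        cw <- c(cw, rep(w, nrow(hit)))
      }
    }
    list(i = ci, j = cj, x = cw)
  })
  ii <- c(ii, cross$i); jj <- c(jj, cross$j); ww <- c(ww, cross$x)
  C <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n),
                            use.last.ij = TRUE)
  out <- new_swd_matrix(C, layout, m_focal$tau_steps, w_exc, w_inh,
                        seed = seed)
  if (collaterals) out <- apply_collaterals(out)
  out
}

validate_matrix <- function(m, check_sign = FALSE) {
  C <- m$C
  n <- attr(m$layout, "n_total")
  if (nrow(C) != n || ncol(C) != n)
    stop("matrix dimension does not match layout")
  if (any(Matrix::diag(C) != 0))
    stop("self-couplings are not allowed (nonzero diagonal entry)")
  if (check_sign) {
    T <- as(C, "TsparseMatrix")
    pops <- node_populations(m$layout)
    src_sign <- POPULATION_SIGN[pops[T@j + 1L]]
    if (any(sign(T@x) != src_sign & T@x != 0))
      stop("edge sign inconsistent with source population")
  }
  invisible(m)
}

#' Write / read a coupling matrix as plain text
#'
#' Serializes an `swd_matrix` to a sparse-triplet text file: a commented
#' header (compartment counts, delay, weight magnitudes, seed) followed by
#' one `i<TAB>j<TAB>weight` line per edge with 0-based indices. The
#' round-trip is lossless.
#'
#' @param m an `swd_matrix`.
#' @param path file path.
#' @return `write_coupling_matrix()` returns `path` invisibly;
#'   `read_coupling_matrix()` returns the `swd_matrix`.
#' @export
write_coupling_matrix <- function(m, path) {
  stopifnot(inherits(m, "swd_matrix"))
  hdr <- c(
    "# swdnet coupling matrix",
    paste0("# counts: ",
           paste(sprintf("%s.%s=%d", m$layout$population, m$layout$region,
                         m$layout$n), collapse = " ")),
    sprintf("# tau_steps: %d", m$tau_steps),
    sprintf("# w_exc: %.17g", m$w_exc),
    sprintf("# w_inh: %.17g", m$w_inh),
    sprintf("# seed: %s", as.character(m$seed))
  )
  T <- as(m$C, "TsparseMatrix")
  ord <- order(T@i, T@j)
  lines <- sprintf("%d\t%d\t%.17g", T@i[ord], T@j[ord], T@x[ord])
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname write_coupling_matrix
#' @export
read_coupling_matrix <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  get_field <- function(key) {
    pat <- paste0("^# ", key, ": ")
    hit <- grep(pat, hdr, value = TRUE)
    if (length(hit) != 1L)
      stop("malformed matrix file: missing header field '", key, "'")
    sub(pat, "", hit)
  }
  counts_str <- strsplit(get_field("counts"), " ", fixed = TRUE)[[1L]]
  kv <- strsplit(counts_str, "=", fixed = TRUE)
  counts <- stats::setNames(
    as.integer(vapply(kv, `[`, "", 2L)),
    vapply(kv, `[`, "", 1L)
  )
  regions <- unique(vapply(strsplit(names(counts), ".", fixed = TRUE),
                           `[`, "", 2L))
  reg_kind <- if (all(regions == "surrounding")) "surrounding"
              else if (!"surrounding" %in% regions) "focal" else "full"
  layout <- network_layout(reg_kind, counts = counts)
  tau_steps <- as.integer(get_field("tau_steps"))
  w_exc <- as.numeric(get_field("w_exc"))
  w_inh <- as.numeric(get_field("w_inh"))
  seed <- suppressWarnings(as.integer(get_field("seed")))
  n <- attr(layout, "n_total")

  body_idx <- which(!is_hdr & nzchar(trimws(lines)))
  if (length(body_idx) == 0L) {
    C <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
    return(new_swd_matrix(C, layout, tau_steps, w_exc, w_inh, seed))
  }
  parts <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed matrix file: cannot parse line ", body_idx[bad[1L]])
  i0 <- as.integer(vapply(parts, `[`, "", 1L))
  j0 <- as.integer(vapply(parts, `[`, "", 2L))
  w <- as.numeric(vapply(parts, `[`, "", 3L))
  bad <- which(is.na(i0) | is.na(j0) | !is.finite(w) |
                 i0 < 0L | j0 < 0L | i0 >= n | j0 >= n)
  if (length(bad))
    stop("malformed matrix file: invalid triplet on line ", body_idx[bad[1L]])
  self <- which(i0 == j0 & w != 0)
  if (length(self))
    stop("invalid matrix file: self-coupling on line ", body_idx[self[1L]])
  C <- Matrix::sparseMatrix(i = i0 + 1L, j = j0 + 1L, x = w, dims = c(n, n))
  m <- new_swd_matrix(C, layout, tau_steps, w_exc, w_inh, seed)
  validate_matrix(m)
  m
}
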