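#' Directed acyclic graph over latent traits
#'
#' Minimal DAG value type: a node vector and a logical adjacency matrix
#' (`amat[i, j]` = edge i -> j). Every constructor/mutation checks acyclicity.
#'
#' @param nodes character vector of node names.
#' @param edges optional 2-column matrix/data.frame of (from, to) edges.
#' @return an object of class `ubt_dag`.
#' @export
dag <- function(nodes, edges = NULL) {
  p <- length(nodes)
  amat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (!is.null(edges) && NROW(edges)) {
    edges <- as.matrix(edges)
    amat[cbind(match(edges[, 1], nodes), match(edges[, 2], nodes))] <- TRUE
  }
  d <- structure(list(nodes = nodes, amat = amat), class = "ubt_dag")
  if (!dag_is_acyclic(d)) config_error("edge set contains a cycle")
  d
}

#' @export
print.ubt_dag <- function(x, ...) {
  e <- dag_edges(x)
  cat(sprintf("<dag> %d nodes, %d edges\n", length(x$nodes), nrow(e)))
  if (nrow(e)) for (i in seq_len(nrow(e)))
    cat(" ", e$from[i], "->", e$to[i], "\n")
  invisible(x)
}

#' @rdname dag
#' @param x a `ubt_dag`.
#' @return `dag_edges`: data.frame of `from`, `to`.
#' @export
dag_edges <- function(x) {
  idx <- which(x$amat, arr.ind = TRUE)
  data.frame(from = x$nodes[idx[, 1]], to = x$nodes[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' @rdname dag
#' @export
dag_is_acyclic <- function(x) amat_acyclic(x$amat)

dag_hash <- function(amat) paste(as.integer(amat), collapse = "")

#' Gaussian BIC score of a DAG
#'
#' Decomposable linear-Gaussian score: for each node, the maximized
#' log-likelihood of its local regression on its parents minus
#' `(log n / 2) * (parents + 2)` (coefficients, intercept and residual
#' variance). Higher is better. A singular parent design scores `-Inf`.
#'
#' @param data numeric matrix/data.frame, animals x nodes, complete.
#' @param g a `ubt_dag` over the columns of `data`.
#' @return the score (scalar). Attribute `by_node` carries the per-node terms.
#' @export
bic_g_score <- function(data, g) {
  x <- as.matrix(data)
  if (anyNA(x)) data_error("network data must be complete")
  n <- nrow(x)
  if (n <= ncol(x)) data_error("need more rows than nodes")
  nodes <- g$nodes
  terms <- vapply(seq_along(nodes), function(j) {
    pa <- which(g$amat[, j])
    node_bic_term(x[, match(nodes[j], colnames(x))],
                  x[, match(nodes[pa], colnames(x)), drop = FALSE], n)
  }, numeric(1))
  structure(sum(terms), by_node = stats::setNames(terms, nodes))
}

node_bic_term <- function(y, xp, n) {
  d <- cbind(1, xp)
  qr_d <- qr(d)
  if (qr_d$rank < ncol(d)) return(-Inf)
  res <- qr.resid(qr_d, y)
  s2 <- sum(res^2) / n
  if (s2 <= 0) return(-Inf)
  ll <- -n / 2 * (log(2 * pi * s2) + 1)
  ll - (log(n) / 2) * (ncol(xp) + 2)
}

# enumerate all single-edge moves from a DAG; returns list of candidate
# (amat, touched-node) entries
dag_moves <- function(amat) {
  p <- nrow(amat)
  moves <- list()
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    if (!amat[i, j] && !amat[j, i]) {
      a2 <- amat; a2[i, j] <- TRUE
      moves[[length(moves) + 1]] <- list(amat = a2, type = "add", i = i, j = j)
    } else if (amat[i, j]) {
      a2 <- amat; a2[i, j] <- FALSE
      moves[[length(moves) + 1]] <- list(amat = a2, type = "delete", i = i, j = j)
      a3 <- amat; a3[i, j] <- FALSE; a3[j, i] <- TRUE
      moves[[length(moves) + 1]] <- list(amat = a3, type = "reverse", i = i, j = j)
    }
  }
  moves
}

amat_acyclic <- function(a) {
  # Kahn elimination on the adjacency matrix
  repeat {
    if (!nrow(a)) return(TRUE)
    sinks <- rowSums(a) == 0
    if (!any(sinks)) return(FALSE)
    if (all(sinks)) return(TRUE)
    a <- a[!sinks, !sinks, drop = FALSE]
  }
}

#' Tabu search over DAG structures
#'
#' Greedy best-move search (add/delete/reverse) maximizing the Gaussian BIC,
#' with a tabu list of recently visited structures: the best non-tabu move is
#' taken even when it worsens the score, and the search stops after
#' `stall` consecutive moves without improving on the best structure seen.
#' Optional random restarts perturb the best DAG with random edge additions.
#'
#' @param data numeric matrix, animals x nodes.
#' @param restarts number of random restarts (default 0: single run from the
#'   empty graph).
#' @param tabu_len length of the tabu list (default 10).
#' @param seed RNG seed (used only by restarts).
#' @param stall stop after this many non-improving moves (default 15).
#' @return the best-scoring `ubt_dag` visited, with attribute `score`.
#' @export
tabu_search <- function(data, restarts = 0, tabu_len = 10, seed = 1L,
                        stall = 15) {
  x <- as.matrix(data)
  if (ncol(x) < 2) config_error("tabu search needs >= 2 nodes")
  nodes <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  colnames(x) <- nodes
  run <- function(start_amat) tabu_run(x, nodes, start_amat, tabu_len, stall)
  best <- run(matrix(FALSE, length(nodes), length(nodes),
                     dimnames = list(nodes, nodes)))
  if (restarts > 0) {
    with_seed(seed, {
      for (r in seq_len(restarts)) {
        a <- best$amat
        # perturb: flip up to 2 random admissible additions
        for (t in 1:2) {
          cand <- which(!a & !t(a) & row(a) != col(a))
          if (!length(cand)) break
          pick <- sample(cand, 1)
          a2 <- a; a2[pick] <- TRUE
          if (amat_acyclic(a2)) a <- a2
        }
        cur <- run(a)
        if (attr(cur, "score") > attr(best, "score")) best <- cur
      }
    })
  }
  best
}

tabu_run <- function(x, nodes, amat, tabu_len, stall) {
  n <- nrow(x)
  score_cache <- new.env(hash = TRUE)
  node_score <- function(j, parents) {
    key <- paste(j, paste(sort(parents), collapse = ","), sep = "|")
    v <- score_cache[[key]]
    if (is.null(v)) {
      v <- node_bic_term(x[, j], x[, parents, drop = FALSE], n)
      score_cache[[key]] <- v
    }
    v
  }
  amat_score <- function(a) sum(vapply(seq_along(nodes), function(j)
    node_score(j, which(a[, j])), numeric(1)))
  cur <- amat
  cur_score <- amat_score(cur)
  best <- cur; best_score <- cur_score
  tabu <- character(tabu_len)
  tabu[1] <- dag_hash(cur)
  ti <- 1L
  no_improve <- 0L
  while (no_improve < stall) {
    moves <- dag_moves(cur)
    cand_best <- NULL; cand_score <- -Inf
    for (mv in moves) {
      if (!amat_acyclic(mv$amat)) next
      if (dag_hash(mv$amat) %in% tabu) next
      # incremental score: only touched nodes change
      delta <- node_score(mv$j, which(mv$amat[, mv$j])) -
        node_score(mv$j, which(cur[, mv$j]))
      if (mv$type == "reverse")
        delta <- delta + node_score(mv$i, which(mv$amat[, mv$i])) -
          node_score(mv$i, which(cur[, mv$i]))
      sc <- cur_score + delta
      if (sc > cand_score) { cand_score <- sc; cand_best <- mv }
    }
    if (is.null(cand_best)) break
    cur <- cand_best$amat
    cur_score <- cand_score
    ti <- ti %% tabu_len + 1L
    tabu[ti] <- dag_hash(cur)
    if (cur_score > best_score + 1e-12) {
      best <- cur; best_score <- cur_score; no_improve <- 0L
    } else no_improve <- no_improve + 1L
  }
  out <- structure(list(nodes = nodes, amat = best), class = "ubt_dag")
  attr(out, "score") <- best_score
  out
}

## ---- constraint phase: MMPC with Fisher-z tests ----------------------------

fisher_z_p <- function(r, n, ncond) {
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  df <- n - ncond - 3
  if (df <= 0) return(1)
  z <- sqrt(df) * atanh(r)
  2 * stats::pnorm(-abs(z))
}

partial_cor <- function(rmat, i, j, s) {
  idx <- c(i, j, s)
  sub <- rmat[idx, idx, drop = FALSE]
  pm <- tryCatch(solve(sub), error = function(e) NULL)
  if (is.null(pm)) return(0)
  -pm[1, 2] / sqrt(pm[1, 1] * pm[2, 2])
}

all_subsets <- function(v, max_size) {
  out <- list(integer(0))
  # index-based combn avoids the scalar-v trap (combn(5, 1) means 1:5)
  for (sz in seq_len(min(length(v), max_size)))
    out <- c(out, utils::combn(seq_along(v), sz,
                               function(i) v[i], simplify = FALSE))
  out
}

#' Max-Min Hill-Climbing structure learning
#'
#' Phase 1 (MMPC): learns a skeleton with Fisher-z partial-correlation
#' independence tests at level `alpha`, using the max-min heuristic for
#' candidate admission, a backward removal pass, and the symmetry correction.
#' Phase 2: greedy hill-climbing on the Gaussian BIC restricted to the
#' learned skeleton.
#'
#' @param data numeric matrix, animals x nodes.
#' @param alpha independence-test level (default 0.05).
#' @param seed unused (the procedure is deterministic); kept for interface
#'   symmetry with [tabu_search()].
#' @param max_cond maximum conditioning-set size (default 3).
#' @return a `ubt_dag` with attribute `score` and attribute `skeleton`.
#' @export
mmhc <- function(data, alpha = 0.05, seed = 1L, max_cond = 3) {
  x <- as.matrix(data)
  if (ncol(x) < 2) config_error("mmhc needs >= 2 nodes")
  nodes <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  colnames(x) <- nodes
  p <- length(nodes); n <- nrow(x)
  rmat <- stats::cor(x)
  # association of (i, j) given candidate set: worst p over conditioning subsets
  max_p <- function(i, j, cset) {
    subsets <- all_subsets(cset, max_cond)
    max(vapply(subsets, function(s)
      fisher_z_p(partial_cor(rmat, i, j, s), n, length(s)), numeric(1)))
  }
  cpc <- vector("list", p)
  for (t in seq_len(p)) {
    cand <- setdiff(seq_len(p), t)
    sel <- integer(0)
    repeat {
      rem <- setdiff(cand, sel)
      if (!length(rem)) break
      ps <- vapply(rem, function(v) max_p(t, v, sel), numeric(1))
      best <- which.min(ps)
      if (ps[best] >= alpha) break
      sel <- c(sel, rem[best])
    }
    # backward pass
    repeat {
      dropped <- FALSE
      for (v in sel) {
        if (max_p(t, v, setdiff(sel, v)) >= alpha) {
          sel <- setdiff(sel, v); dropped <- TRUE; break
        }
      }
      if (!dropped) break
    }
    cpc[[t]] <- sel
  }
  skel <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  for (t in seq_len(p)) for (v in cpc[[t]])
    if (t %in% cpc[[v]]) skel[t, v] <- skel[v, t] <- TRUE   # symmetry
  out <- hill_climb_restricted(x, nodes, skel)
  attr(out, "skeleton") <- skel
  out
}

hill_climb_restricted <- function(x, nodes, skel) {
  n <- nrow(x); p <- length(nodes)
  amat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  node_score <- function(j, parents) node_bic_term(x[, j], x[, parents, drop = FALSE], n)
  scores <- vapply(seq_len(p), function(j) node_score(j, integer(0)), numeric(1))
  repeat {
    best_delta <- 1e-10; best_mv <- NULL
    for (mv in dag_moves(amat)) {
      if (mv$type == "add" && !skel[mv$i, mv$j]) next
      if (!amat_acyclic(mv$amat)) next
      delta <- node_score(mv$j, which(mv$amat[, mv$j])) - scores[mv$j]
      if (mv$type == "reverse")
        delta <- delta + node_score(mv$i, which(mv$amat[, mv$i])) - scores[mv$i]
      if (delta > best_delta) { best_delta <- delta; best_mv <- mv }
    }
    if (is.null(best_mv)) break
    amat <- best_mv$amat
    scores[best_mv$j] <- node_score(best_mv$j, which(amat[, best_mv$j]))
    if (best_mv$type == "reverse")
      scores[best_mv$i] <- node_score(best_mv$i, which(amat[, best_mv$i]))
  }
  out <- structure(list(nodes = nodes, amat = amat), class = "ubt_dag")
  attr(out, "score") <- sum(scores)
  out
}

#' Bootstrap-averaged network
#'
#' Learns a structure on `n_boot` nonparametric resamples of the animals,
#' tallies, per undirected pair, the fraction of networks containing the edge
#' (strength) and, among those, the fraction per orientation (direction), and
#' forms a consensus DAG keeping edges with `strength >= strength_threshold`
#' oriented by `direction >= 0.5`. Direction ties at exactly 0.5 keep the
#' edge with the lexicographically smaller origin, with a logged note; a
#' cyclic consensus is repaired by dropping the weakest-direction edge.
#'
#' @param data numeric matrix, animals x nodes.
#' @param learner function(data) -> `ubt_dag` (e.g. a wrapped
#'   [tabu_search()] or [mmhc()]).
#' @param n_boot number of resamples (>= 100; default 500).
#' @param seed RNG seed for the resample indices.
#' @param strength_threshold consensus strength threshold (default 0.5).
#' @return an object of class `averaged_network`: `edges` (per-pair strength
#'   and directions), `consensus` (`ubt_dag`), `n_boot`, `notes`.
#' @export
bootstrap_average <- function(data, learner, n_boot = 500, seed = 1L,
                              strength_threshold = 0.5) {
  if (n_boot < 100) config_error("n_boot must be >= 100")
  x <- as.matrix(data)
  nodes <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  colnames(x) <- nodes
  p <- length(nodes)
  counts <- matrix(0, p, p, dimnames = list(nodes, nodes))  # directed tallies
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(x), replace = TRUE)
      g <- learner(x[idx, , drop = FALSE])
      counts <- counts + g$amat
    }
  })
  pairs <- which(upper.tri(counts), arr.ind = TRUE)
  edges <- data.frame(
    from = nodes[pairs[, 1]], to = nodes[pairs[, 2]],
    strength = (counts[pairs] + t(counts)[pairs]) / n_boot,
    dir_fwd = NA_real_, dir_rev = NA_real_, stringsAsFactors = FALSE)
  tot <- counts[pairs] + t(counts)[pairs]
  nz <- tot > 0
  edges$dir_fwd[nz] <- counts[pairs][nz] / tot[nz]
  edges$dir_rev[nz] <- 1 - edges$dir_fwd[nz]
  notes <- character(0)
  keep <- edges$strength >= strength_threshold
  cons <- edges[keep, , drop = FALSE]
  cons_edges <- NULL
  if (nrow(cons)) {
    fwd <- cons$dir_fwd >= 0.5
    tie <- abs(cons$dir_fwd - 0.5) < 1e-12
    if (any(tie))
      notes <- c(notes, sprintf(
        "direction tie at 0.5 for %s -- %s: oriented lexicographically",
        cons$from[tie], cons$to[tie]))
    cons_edges <- data.frame(
      from = ifelse(fwd, cons$from, cons$to),
      to = ifelse(fwd, cons$to, cons$from),
      strength = cons$strength,
      direction = pmax(cons$dir_fwd, cons$dir_rev),
      stringsAsFactors = FALSE)
  }
  consensus <- consensus_dag(nodes, cons_edges, notes)
  structure(list(edges = edges, consensus = consensus$dag,
                 consensus_edges = consensus$edges,
                 n_boot = n_boot, strength_threshold = strength_threshold,
                 notes = consensus$notes),
            class = "averaged_network")
}

consensus_dag <- function(nodes, cons_edges, notes) {
  if (is.null(cons_edges) || !nrow(cons_edges))
    return(list(dag = dag(nodes), edges = cons_edges, notes = notes))
  repeat {
    d <- tryCatch(dag(nodes, cons_edges[, c("from", "to")]),
                  error = function(e) NULL)
    if (!is.null(d)) return(list(dag = d, edges = cons_edges, notes = notes))
    worst <- which.min(cons_edges$direction)
    notes <- c(notes, sprintf(
      "cyclic consensus: dropped weakest-direction edge %s -> %s (dir %.2f)",
      cons_edges$from[worst], cons_edges$to[worst], cons_edges$direction[worst]))
    cons_edges <- cons_edges[-worst, , drop = FALSE]
  }
}

#' @export
print.averaged_network <- function(x, ...) {
  cat(sprintf("<averaged_network> %d bootstrap replicates, %d consensus edge(s)\n",
              x$n_boot, nrow(dag_edges(x$consensus))))
  sig <- x$edges[x$edges$strength > 0, , drop = FALSE]
  if (nrow(sig)) print(sig, row.names = FALSE)
  invisible(x)
}

#' Compare two averaged networks
#'
#' Edge-level diff by undirected pair: edges present only in `b` (gained),
#' only in `a` (lost), present in both with flipped consensus orientation
#' (reoriented), plus strength/direction deltas.
#'
#' @param a,b `averaged_network` objects over the same node set.
#' @return data.frame with one row per differing pair: `pair`, `status`,
#'   `strength_a`, `strength_b`, `delta_strength`.
#' @export
compare_networks <- function(a, b) {
  stopifnot(inherits(a, "averaged_network"), inherits(b, "averaged_network"))
  if (!setequal(a$consensus$nodes, b$consensus$nodes))
    config_error("networks must share the same node set")
  ea <- dag_edges(a$consensus)
  eb <- dag_edges(b$consensus)
  pkey <- function(f, t) paste(pmin(f, t), pmax(f, t), sep = "--")
  dkey <- function(f, t) paste(f, t, sep = "->")
  pa <- if (nrow(ea)) pkey(ea$from, ea$to) else character(0)
  pb <- if (nrow(eb)) pkey(eb$from, eb$to) else character(0)
  all_pairs <- union(pa, pb)
  strength_of <- function(net, pair) {
    k <- pkey(net$edges$from, net$edges$to)
    i <- match(pair, k)
    ifelse(is.na(i), 0, net$edges$strength[i])
  }
  status <- vapply(all_pairs, function(pr) {
    ina <- pr %in% pa; inb <- pr %in% pb
    if (ina && inb) {
      da <- dkey(ea$from, ea$to)[match(pr, pa)]
      db <- dkey(eb$from, eb$to)[match(pr, pb)]
      if (da == db) "same" else "reoriented"
    } else if (inb) "gained" else "lost"
  }, character(1))
  out <- data.frame(pair = all_pairs, status = unname(status),
                    strength_a = strength_of(a, all_pairs),
                    strength_b = strength_of(b, all_pairs),
                    stringsAsFactors = FALSE)
  out$delta_strength <- out$strength_b - out$strength_a
  out[out$status != "same", , drop = FALSE]
}

#' Export an averaged network as edge-list CSV and DOT text
#'
#' @param net an `averaged_network`.
#' @param stem output path prefix; writes `<stem>.csv` and `<stem>.dot`.
#' @return `stem`, invisibly.
#' @export
export_network <- function(net, stem) {
  utils::write.csv(net$edges, paste0(stem, ".csv"), row.names = FALSE)
  e <- dag_edges(net$consensus)
  lines <- c("digraph consensus {",
             paste0("  \"", net$consensus$nodes, "\";"),
             if (nrow(e)) sprintf("  \"%s\" -> \"%s\";", e$from, e$to),
             "}")
  writeLines(lines, paste0(stem, ".dot"))
  invisible(stem)
}
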