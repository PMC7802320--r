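#' Assemble a dataset for causal discovery
#'
#' Combines binary deletion indicators, (normalized) immune expression and
#' recurrence-free survival into one sample-by-variable matrix. By default
#' the outcome column is the observed RFS time restricted to samples whose
#' event was observed (censoring-aware conditional-independence testing is
#' out of scope); rows with missing values are dropped listwise.
#'
#' @param carriers A `carrier_matrix`.
#' @param expr An [expression_matrix].
#' @param time,event RFS outcome per carrier-matrix row.
#' @param dsv_ids,gene_ids Variables to include.
#' @param events_only Restrict to event-observed samples (default `TRUE`).
#' @return List of class `causal_dataset`: `data` (matrix), `roles` (named
#'   `"dsv"`, `"expression"` or `"outcome"` per column).
#' @export
build_causal_dataset <- function(carriers, expr, time, event, dsv_ids,
                                 gene_ids, events_only = TRUE) {
  X <- carriers$carriers
  samples <- intersect(rownames(X), colnames(expr$values))
  keep <- samples
  if (events_only) {
    ev <- event[match(keep, rownames(X))]
    keep <- keep[!is.na(ev) & ev == 1]
  }
  dat <- cbind(X[keep, dsv_ids, drop = FALSE],
               t(expr$values[gene_ids, keep, drop = FALSE]),
               RFS = time[match(keep, rownames(X))])
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  roles <- c(rep("dsv", length(dsv_ids)), rep("expression", length(gene_ids)),
             "outcome")
  names(roles) <- colnames(dat)
  if (ncol(dat) < 3) stop("causal dataset needs >= 3 variables")
  structure(list(data = dat, roles = roles), class = "causal_dataset")
}

#' Fisher-z conditional independence test
#'
#' Partial correlation of variables `i` and `j` given the conditioning set
#' `S`, via inversion of the corresponding correlation submatrix, then
#' `z = sqrt(n - |S| - 3) * atanh(rho)` against the standard normal
#' (two-sided).
#'
#' @param data Numeric sample-by-variable matrix (or `causal_dataset`).
#' @param i,j Column indices (or names) of the tested pair.
#' @param S Conditioning set (indices/names), possibly empty.
#' @return The p-value.
#' @export
ci_test_fisher_z <- function(data, i, j, S = integer(0)) {
  if (inherits(data, "causal_dataset")) data <- data$data
  n <- nrow(data)
  if (n - length(S) - 3 <= 0)
    stop("too few samples for a conditioning set of size ", length(S))
  sub <- c(i, j, S)
  C <- stats::cor(data[, sub, drop = FALSE])
  if (length(S) == 0) {
    rho <- C[1, 2]  # marginal case; also covers |rho| = 1 exactly
  } else {
    P <- tryCatch(solve(C), error = function(e)
      stop("singular correlation submatrix in CI test"))
    rho <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  }
  rho <- min(max(rho, -1 + 1e-12), 1 - 1e-12)
  z <- sqrt(n - length(S) - 3) * atanh(rho)
  2 * stats::pnorm(-abs(z))
}

#' Stable-PC skeleton estimation
#'
#' Order-independent ("stable") skeleton phase of the PC algorithm: start
#' from the complete graph; for conditioning-set sizes `l = 0, 1, 2, ...`
#' remove edge `(i, j)` if some subset `S` of the level-`l` snapshot of
#' `adj(i) \\ {j}` gives a CI-test p-value above `alpha`, recording `S` as
#' the separation set.
#'
#' @param data Sample-by-variable matrix or `causal_dataset`.
#' @param alpha Significance level in (0, 1).
#' @param max_order Cap on the conditioning-set size.
#' @return List with `adj` (symmetric logical adjacency), `sepsets`
#'   (list-of-lists, `sepsets[[i]][[j]]` = separating set or `NULL`),
#'   `alpha`, `n_tests`.
#' @export
pc_skeleton <- function(data, alpha = 0.05, max_order = Inf) {
  if (inherits(data, "causal_dataset")) data <- data$data
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  p <- ncol(data)
  vars <- colnames(data) %||% sprintf("V%d", seq_len(p))
  colnames(data) <- vars
  adj <- matrix(TRUE, p, p, dimnames = list(vars, vars))
  diag(adj) <- FALSE
  sepsets <- lapply(seq_len(p), function(i) vector("list", p))
  n_tests <- 0L
  ell <- 0L
  repeat {
    snapshot <- adj
    any_candidate <- FALSE
    for (i in seq_len(p)) {
      nbrs_i <- which(snapshot[i, ])
      for (j in nbrs_i) {
        if (!adj[i, j]) next
        pool <- setdiff(which(snapshot[i, ]), j)
        if (length(pool) < ell) next
        any_candidate <- TRUE
        sets <- if (ell == 0L) list(integer(0))
          else if (length(pool) == ell) list(pool)  # combn(scalar, m) trap
          else utils::combn(pool, ell, simplify = FALSE)
        for (S in sets) {
          pval <- ci_test_fisher_z(data, i, j, S)
          n_tests <- n_tests + 1L
          if (pval > alpha) {
            adj[i, j] <- adj[j, i] <- FALSE
            sepsets[[i]][[j]] <- sepsets[[j]][[i]] <- S
            break
          }
        }
      }
    }
    ell <- ell + 1L
    if (!any_candidate || ell > max_order) break
    if (max(rowSums(adj)) - 1 < ell) break
  }
  list(adj = adj, sepsets = sepsets, alpha = alpha, n_tests = n_tests,
       vars = vars)
}

#' Orient a skeleton into a CPDAG
#'
#' Detects v-structures `x -> z <- y` (nonadjacent `x`, `y` with a common
#' neighbor `z` outside their separation set), then applies Meek rules 1-4
#' to closure. Conflicting orientations are left undirected and logged.
#' The directed part of the output is verified acyclic.
#'
#' @param skeleton Output of [pc_skeleton()].
#' @return List of class `cpdag`: `amat` (logical; `amat[i, j]` means an
#'   edge i-j with an arrowhead at j; both TRUE = undirected), `vars`,
#'   `sepsets`, `alpha`, `conflicts`.
#' @export
orient_edges <- function(skeleton) {
  adj <- skeleton$adj
  sepsets <- skeleton$sepsets
  p <- nrow(adj)
  amat <- adj  # both directions TRUE = undirected
  conflicts <- 0L

  orient <- function(a, b) {
    # a -> b unless already oriented b -> a (conflict: keep undirected)
    if (amat[a, b] && !amat[b, a]) return(invisible())
    if (!amat[a, b] && amat[b, a]) {
      amat[a, b] <<- TRUE
      conflicts <<- conflicts + 1L
      return(invisible())
    }
    amat[b, a] <<- FALSE
  }

  # v-structures
  for (z in seq_len(p)) {
    nb <- which(adj[z, ])
    if (length(nb) < 2) next
    for (x in nb) for (y in nb) {
      if (x >= y || adj[x, y]) next
      S <- sepsets[[x]][[y]]
      if (!is.null(S) && z %in% S) next
      orient(x, z); orient(y, z)
    }
  }

  directed <- function(a, b) amat[a, b] && !amat[b, a]
  undirected <- function(a, b) amat[a, b] && amat[b, a]
  adjacent <- function(a, b) amat[a, b] || amat[b, a]

  # Meek rules to closure
  repeat {
    changed <- FALSE
    for (a in seq_len(p)) for (b in seq_len(p)) {
      if (a == b || !undirected(a, b)) next
      # R1: c -> a, a - b, c and b nonadjacent  =>  a -> b
      for (c in seq_len(p)) {
        if (c != b && directed(c, a) && !adjacent(c, b)) {
          orient(a, b); changed <- TRUE; break
        }
      }
      if (!undirected(a, b)) next
      # R2: a -> c -> b and a - b  =>  a -> b
      for (c in seq_len(p)) {
        if (c != a && c != b && directed(a, c) && directed(c, b)) {
          orient(a, b); changed <- TRUE; break
        }
      }
      if (!undirected(a, b)) next
      # R3: a - c -> b, a - d -> b, c and d nonadjacent  =>  a -> b
      cand <- which(vapply(seq_len(p), function(c)
        c != a && c != b && undirected(a, c) && directed(c, b), logical(1)))
      if (length(cand) >= 2) {
        for (c in cand) for (d in cand) {
          if (c < d && !adjacent(c, d)) {
            orient(a, b); changed <- TRUE; break
          }
        }
      }
      if (!undirected(a, b)) next
      # R4: a - c, c -> d, d -> b, c and b nonadjacent, a adjacent to d
      for (c in seq_len(p)) {
        if (c == a || c == b || !undirected(a, c) || adjacent(c, b)) next
        for (d in seq_len(p)) {
          if (d != a && d != b && d != c && directed(c, d) && directed(d, b) &&
              adjacent(a, d)) {
            orient(a, b); changed <- TRUE; break
          }
        }
        if (!undirected(a, b)) break
      }
    }
    if (!changed) break
  }

  # acyclicity of the strictly-directed subgraph
  D <- amat & !t(amat)
  if (has_directed_cycle(D)) stop("internal error: oriented graph has a directed cycle")
  if (conflicts > 0) message(conflicts, " orientation conflict(s) left undirected")
  structure(list(amat = amat, vars = skeleton$vars, sepsets = sepsets,
                 alpha = skeleton$alpha, conflicts = conflicts),
            class = "cpdag")
}

has_directed_cycle <- function(D) {
  p <- nrow(D)
  indeg <- colSums(D)
  active <- rep(TRUE, p)
  repeat {
    src <- which(active & indeg == 0)
    if (length(src) == 0) break
    for (s in src) {
      indeg[D[s, ]] <- indeg[D[s, ]] - 1L
      active[s] <- FALSE
    }
  }
  any(active)
}

#' Run the PC algorithm end to end
#'
#' @param data Sample-by-variable matrix or `causal_dataset`.
#' @param alpha CI-test significance level.
#' @return A `cpdag`.
#' @export
pc_algorithm <- function(data, alpha = 0.05) {
  orient_edges(pc_skeleton(data, alpha = alpha))
}

#' Extract deletion -> gene -> outcome mediation paths from a CPDAG
#'
#' Returns all length-2 paths from a deletion node through a mediator to
#' the outcome. Paths with both hops strictly directed are `"directed"`;
#' paths where a hop is undirected (so some member of the equivalence
#' class orients it forward) are `"compatible"`.
#'
#' @param g A `cpdag`.
#' @param dsv_nodes Names of the deletion variables.
#' @param outcome Name of the outcome node.
#' @return data.frame with `dsv`, `mediator`, `status`.
#' @export
find_mediation_paths <- function(g, dsv_nodes, outcome) {
  stopifnot(inherits(g, "cpdag"))
  if (!outcome %in% g$vars) stop("outcome node '", outcome, "' absent from graph")
  amat <- g$amat
  vars <- g$vars
  hop <- function(a, b) {
    if (amat[a, b] && !amat[b, a]) return("directed")
    if (amat[a, b] && amat[b, a]) return("undirected")
    "none"
  }
  rows <- list()
  mediators <- setdiff(vars, c(dsv_nodes, outcome))
  for (d in intersect(dsv_nodes, vars)) for (m in mediators) {
    h1 <- hop(d, m); h2 <- hop(m, outcome)
    if (h1 == "none" || h2 == "none") next
    status <- if (h1 == "directed" && h2 == "directed") "directed" else "compatible"
    rows[[length(rows) + 1L]] <- data.frame(dsv = d, mediator = m,
                                            status = status,
                                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(dsv = character(0), mediator = character(0),
                      status = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Export a CPDAG as an edge list
#' @param g A `cpdag`.
#' @return data.frame with `from`, `to`, `type` (`directed`/`undirected`);
#'   undirected edges appear once.
#' @export
cpdag_edges <- function(g) {
  stopifnot(inherits(g, "cpdag"))
  amat <- g$amat; vars <- g$vars
  rows <- list()
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    if (i == j || !amat[i, j]) next
    if (amat[j, i] && i > j) next  # emit undirected once
    rows[[length(rows) + 1L]] <- data.frame(
      from = vars[i], to = vars[j],
      type = if (amat[j, i]) "undirected" else "directed",
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(from = character(0), to = character(0),
                      type = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
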