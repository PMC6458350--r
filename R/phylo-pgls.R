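# Phylogenetic generalized least squares under Brownian motion.
#
# The Brownian covariance of a pair of tips is the shared root-to-tip
# path length (depth of their most recent common ancestor). The GLS fit
# is closed form -- no lambda or other covariance parameters are
# estimated: beta = (X' C^-1 X)^-1 X' C^-1 y.

#' Read a rooted Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that additionally checks what the
#' downstream Brownian model needs: branch lengths present and
#' non-negative, tip labels unique.
#'
#' @param path Path to a Newick file, or (if `text` is used) a string.
#' @param text Optional Newick string, bypassing `path`.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text)
          else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick input", call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("tree has negative branch lengths", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  tree
}

# Root-to-node path length for every node of a phylo tree.
node_depths <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  depth <- rep(NA_real_, n_node)
  root <- n_tip + 1L
  depth[root] <- 0
  # edges in preorder so parents are always filled before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    depth[child] <- depth[par] + ord$edge.length[e]
  }
  depth
}

#' Brownian-motion covariance matrix of a tree
#'
#' Entry (i, j) is the depth (root-to-node path length) of the most
#' recent common ancestor of tips i and j; the diagonal holds the
#' root-to-tip depths. Computed by walking each tip's ancestor path;
#' no reliance on the tree being ultrametric.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param tips_order Optional character vector giving the row/column
#'   order; must be a permutation of the tip labels.
#' @return A symmetric positive semi-definite matrix with dimnames.
#' @export
bm_covariance <- function(tree, tips_order = tree$tip.label) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object",
                                     call. = FALSE)
  unknown <- setdiff(tips_order, tree$tip.label)
  if (length(unknown) > 0) {
    stop("unknown tip name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(tips_order) != length(tree$tip.label) ||
      anyDuplicated(tips_order)) {
    stop("`tips_order` must be a permutation of the tip labels",
         call. = FALSE)
  }
  n_tip <- length(tree$tip.label)
  depth <- node_depths(tree)
  parent <- rep(NA_integer_, n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  # ancestor set (including self) per tip
  anc <- lapply(seq_len(n_tip), function(tip) {
    path <- tip
    while (!is.na(parent[path[length(path)]])) {
      path <- c(path, parent[path[length(path)]])
    }
    path
  })
  C <- matrix(0, n_tip, n_tip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n_tip)) {
    C[i, i] <- depth[i]
    if (i < n_tip) for (j in seq(i + 1, n_tip)) {
      common <- intersect(anc[[i]], anc[[j]])
      mrca <- common[which.max(depth[common])]
      C[i, j] <- C[j, i] <- depth[mrca]
    }
  }
  C[tips_order, tips_order]
}

#' Phylogenetic generalized least squares (Brownian motion)
#'
#' Fits y = b0 + b1 x by generalized least squares with error covariance
#' sigma^2 C, where C is the Brownian covariance of the supplied tree.
#' Estimation is closed form via the Cholesky factor of C (equivalently,
#' OLS on the whitened variables). The slope's significance is the
#' squared t ratio referred to F(1, n - 2); R^2 is the GLS-weighted
#' coefficient of determination, 1 - RSS/TSS with both sums taken in the
#' whitened metric and TSS about the GLS mean of y.
#'
#' @param data A data frame with one row per species.
#' @param response,predictor Columns of `data` (tidy-eval).
#' @param tree A `phylo` tree whose tip labels match `species`.
#' @param species Column of `data` holding species names matching the
#'   tree's tips (tidy-eval; default `species`).
#' @param transform Transformation applied to both variables before
#'   fitting: `"none"`, `"log10"`, `"sqrt"`, `"fourth_root"`, or
#'   `"fraction_of_circle"` (divides each variable by the specimen's
#'   circular circumference 2 pi r, turning an arc length into a fraction
#'   of its circle; requires `r_col`).
#' @param transform_y,transform_x Per-variable overrides of `transform`
#'   (same choices), e.g. `transform_y = "sqrt"` to linearize an area
#'   against a length.
#' @param r_col Column holding the radius of curvature, used only by the
#'   `"fraction_of_circle"` transform (tidy-eval; default `r`).
#' @return An object of class `pgls_fit`; see [tidy.pgls_fit()] and
#'   [glance.pgls_fit()].
#' @examples
#' tr <- simulate_pure_birth_tree(32, seed = 1)
#' d <- simulate_bm_regression(tr, intercept = 1, slope = 0.5,
#'                             sigma2 = 0.1, seed = 2)
#' fit <- pgls_fit(d, y, x, tree = tr)
#' glance(fit)
#' @export
pgls_fit <- function(data, response, predictor, tree,
                     species = species,
                     transform = c("none", "log10", "sqrt", "fourth_root",
                                   "fraction_of_circle"),
                     transform_y = NULL, transform_x = NULL,
                     r_col = r) {
  choices <- c("none", "log10", "sqrt", "fourth_root",
               "fraction_of_circle")
  transform <- match.arg(transform)
  transform_y <- if (is.null(transform_y)) transform
                 else match.arg(transform_y, choices)
  transform_x <- if (is.null(transform_x)) transform
                 else match.arg(transform_x, choices)
  response <- rlang::enquo(response)
  predictor <- rlang::enquo(predictor)
  species <- rlang::enquo(species)
  r_col <- rlang::enquo(r_col)

  sp <- as.character(rlang::eval_tidy(species, data))
  y <- as.numeric(rlang::eval_tidy(response, data))
  x <- as.numeric(rlang::eval_tidy(predictor, data))

  keep <- sp %in% tree$tip.label & is.finite(y) & is.finite(x)
  unmatched <- unique(sp[!sp %in% tree$tip.label])
  if (length(unmatched) > 0) {
    warning("dropping species absent from the tree: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  sp <- sp[keep]; y <- y[keep]; x <- x[keep]
  if (anyDuplicated(sp)) {
    stop("multiple rows per species; aggregate to one value per species ",
         "before fitting", call. = FALSE)
  }
  n <- length(y)
  if (n < 3) stop("need at least 3 matched species", call. = FALSE)

  tf <- function(v, transform) switch(transform,
    none = v,
    log10 = {
      if (any(v <= 0)) stop("log10 transform requires positive values",
                            call. = FALSE)
      log10(v)
    },
    sqrt = {
      if (any(v < 0)) stop("sqrt transform requires non-negative values",
                           call. = FALSE)
      sqrt(v)
    },
    fourth_root = {
      if (any(v < 0)) stop("fourth-root transform requires non-negative ",
                           "values", call. = FALSE)
      v^0.25
    },
    fraction_of_circle = {
      r <- as.numeric(rlang::eval_tidy(r_col, data))[keep]
      if (any(!is.finite(r) | r <= 0)) {
        stop("fraction_of_circle transform needs positive radii in `",
             rlang::as_label(r_col), "`", call. = FALSE)
      }
      v / (2 * pi * r)
    }
  )
  y <- tf(y, transform_y); x <- tf(x, transform_x)
  transform_label <- if (transform_y == transform_x) transform_y else {
    paste0("y:", transform_y, ",x:", transform_x)
  }

  # prune to the matched species; covariance in data order
  drop_tips <- setdiff(tree$tip.label, sp)
  if (length(drop_tips) > 0) tree <- ape::drop.tip(tree, drop_tips)
  C <- bm_covariance(tree, tips_order = sp)

  L <- tryCatch(chol(C), error = function(e) {
    stop("Brownian covariance matrix is singular (zero-length terminal ",
         "branches?)", call. = FALSE)
  })
  # whiten: solve L' z = v  (C = L'L with R's upper-triangular chol)
  wy <- backsolve(L, y, transpose = TRUE)
  X <- cbind(`(Intercept)` = 1, x = x)
  wX <- backsolve(L, X, transpose = TRUE)

  xtx <- crossprod(wX)
  beta <- stats::setNames(as.numeric(solve(xtx, crossprod(wX, wy))),
                          colnames(X))
  fitted <- as.numeric(X %*% beta)
  resid <- y - fitted
  wresid <- wy - wX %*% beta
  rss <- sum(wresid^2)
  df_resid <- n - 2L
  sigma2 <- rss / df_resid
  se <- stats::setNames(sqrt(diag(solve(xtx)) * sigma2), colnames(X))
  t_slope <- beta[["x"]] / se[["x"]]
  f_stat <- t_slope^2
  p <- stats::pf(f_stat, 1, df_resid, lower.tail = FALSE)
  # GLS-weighted mean of y: GLS intercept-only fit
  w1 <- backsolve(L, rep(1, n), transpose = TRUE)
  gls_mean <- sum(w1 * wy) / sum(w1^2)
  tss <- sum((wy - w1 * gls_mean)^2)
  r2 <- 1 - rss / tss

  structure(list(
    coefficients = beta,
    se = se,
    sigma2 = sigma2,
    r_squared = r2,
    f_statistic = f_stat,
    df = c(1L, df_resid),
    p_value = p,
    n = n,
    transform = transform_label,
    transform_y = transform_y,
    transform_x = transform_x,
    species = sp,
    x = x, y = y,
    fitted = fitted,
    residuals = resid,
    response = rlang::as_label(response),
    predictor = rlang::as_label(predictor)
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS (Brownian motion), n =", x$n, "\n")
  cat("  ", x$response, "~", x$predictor,
      if (x$transform != "none") paste0("[", x$transform, "]"), "\n")
  cat(sprintf("  intercept = %.4g, slope = %.4g (se %.3g)\n",
              x$coefficients[1], x$coefficients[2], x$se[2]))
  cat(sprintf("  sigma^2 = %.4g, R^2 = %.3f, F(1, %d) = %.2f, p = %.3g\n",
              x$sigma2, x$r_squared, x$df[2], x$f_statistic, x$p_value))
  invisible(x)
}

#' Tidy a PGLS fit
#'
#' @param x A [pgls_fit()] object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy pgls_fit
#' @export
tidy.pgls_fit <- function(x, ...) {
  t_vals <- unname(x$coefficients / x$se)
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = t_vals,
    p.value = 2 * stats::pt(abs(t_vals), x$df[2], lower.tail = FALSE)
  )
}

#' One-row summary of a PGLS fit
#'
#' @inheritParams tidy.pgls_fit
#' @return A one-row tibble: `intercept`, `slope`, `sigma2`, `r.squared`,
#'   `statistic` (F for the slope), `df`, `df.residual`, `p.value`,
#'   `transform`, `n`.
#' @method glance pgls_fit
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(
    intercept = unname(x$coefficients[1]),
    slope = unname(x$coefficients[2]),
    sigma2 = x$sigma2,
    r.squared = x$r_squared,
    statistic = x$f_statistic,
    df = x$df[1],
    df.residual = x$df[2],
    p.value = x$p_value,
    transform = x$transform,
    n = x$n
  )
}

#' Plot a PGLS fit
#'
#' Scatter of the (transformed) data with the fitted PGLS line.
#'
#' @param object A [pgls_fit()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pgls_fit
#' @export
autoplot.pgls_fit <- function(object, ...) {
  d <- tibble::tibble(x = object$x, y = object$y)
  lab <- function(v, tf) if (tf == "none") v else paste0(tf, "(", v, ")")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$coefficients[1],
                         slope = object$coefficients[2],
                         colour = "steelblue") +
    ggplot2::labs(x = lab(object$predictor, object$transform_x),
                  y = lab(object$response, object$transform_y))
}
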