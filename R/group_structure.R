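#' Build an overlapping group structure
#'
#' Represents a collection of possibly-overlapping variable groups together
#' with the sparse 0/1 latent expansion map `A` whose block for group `g`
#' places the |g| latent coordinates of that group onto the variables in
#' `g`.  Collapsed coefficients are `beta = A %*% gamma`; each latent
#' coordinate belongs to exactly one group, so blocks of `gamma` can be
#' soft-thresholded independently even when groups share variables.
#'
#' Variables that appear in no membership pair become penalized singleton
#' groups, so the expansion always spans all `p` variables.  Variables
#' listed in `unpenalized` are removed from any user group they appear in
#' and handled as zero-weight singleton groups (they receive a plain
#' gradient step in the solver).
#'
#' @param memberships a two-column data frame (or matrix) of
#'   `(variable_index, group_label)` pairs; a variable repeated under
#'   several labels encodes overlap.  Column names are ignored; order is
#'   (variable, group).
#' @param n_variables total number of variables `p`; indices are 1-based.
#' @param unpenalized integer vector of variable indices excluded from
#'   regularization.
#'
#' @return an object of class `"group_structure"` with elements
#'   `p`, `groups` (named list of integer index vectors, ordered by first
#'   appearance of the label, then auto-completed singletons in index
#'   order), `sizes`, `penalized` (logical per group), `latent_dim`
#'   (`sum(sizes)`), `block` (integer vector mapping each latent coordinate
#'   to its group), and `A` (sparse `p x latent_dim` expansion map).
#' @export
#' @examples
#' m <- data.frame(variable = c(2, 3, 3, 4), group = c("a", "a", "b", "b"))
#' gs <- group_structure(m, n_variables = 5)
#' gs$latent_dim  # 2 + 2 + singletons for variables 1 and 5
group_structure <- function(memberships, n_variables, unpenalized = integer()) {
  if (!is.numeric(n_variables) || length(n_variables) != 1L ||
      is.na(n_variables) || n_variables < 1 || n_variables %% 1 != 0) {
    stop("`n_variables` must be a single positive integer", call. = FALSE)
  }
  p <- as.integer(n_variables)

  memberships <- as.data.frame(memberships)
  if (ncol(memberships) < 2L || nrow(memberships) < 1L) {
    stop("`memberships` must have at least one (variable, group) pair",
         call. = FALSE)
  }
  var <- memberships[[1L]]
  grp <- as.character(memberships[[2L]])
  if (!is.numeric(var) || anyNA(var) || any(var %% 1 != 0)) {
    stop("variable indices must be integers", call. = FALSE)
  }
  var <- as.integer(var)
  bad <- var < 1L | var > p
  if (any(bad)) {
    stop(sprintf("variable index %d is outside [1, %d]",
                 var[which(bad)[1L]], p), call. = FALSE)
  }
  key <- paste(var, grp, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop(sprintf("duplicate membership pair: variable %s in group '%s'",
                 sub("\r.*", "", d), sub(".*\r", "", d)), call. = FALSE)
  }

  unpenalized <- .check_indices(unpenalized, p, "unpenalized")

  labs <- unique(grp)
  groups <- split(var, factor(grp, levels = labs))
  if (length(unpenalized)) {
    groups <- lapply(groups, function(g) g[!g %in% unpenalized])
    keep <- lengths(groups) > 0L
    groups <- groups[keep]
    labs <- labs[keep]
  }
  penalized <- rep(TRUE, length(groups))

  covered <- unique(unlist(groups, use.names = FALSE))
  auto <- setdiff(seq_len(p), c(covered, unpenalized))
  if (length(auto)) {
    groups <- c(groups, as.list(auto))
    labs <- c(labs, paste0(".v", auto))
    penalized <- c(penalized, rep(TRUE, length(auto)))
  }
  if (length(unpenalized)) {
    groups <- c(groups, as.list(sort(unpenalized)))
    labs <- c(labs, paste0(".v", sort(unpenalized)))
    penalized <- c(penalized, rep(FALSE, length(unpenalized)))
  }
  names(groups) <- labs

  sizes <- lengths(groups)
  d <- sum(sizes)
  block <- rep.int(seq_along(groups), sizes)
  A <- Matrix::sparseMatrix(i = unlist(groups, use.names = FALSE),
                            j = seq_len(d), x = 1, dims = c(p, d))

  structure(list(p = p, groups = groups, sizes = sizes,
                 penalized = penalized, latent_dim = d,
                 block = block, A = A),
            class = "group_structure")
}

.check_indices <- function(idx, p, what) {
  if (is.null(idx) || !length(idx)) return(integer())
  if (!is.numeric(idx) || anyNA(idx) || any(idx %% 1 != 0)) {
    stop(sprintf("`%s` must contain integer variable indices", what),
         call. = FALSE)
  }
  idx <- unique(as.integer(idx))
  if (any(idx < 1L | idx > p)) {
    stop(sprintf("`%s` index %d is outside [1, %d]", what,
                 idx[which(idx < 1L | idx > p)[1L]], p), call. = FALSE)
  }
  idx
}

#' @export
print.group_structure <- function(x, ...) {
  cat(sprintf(
    "Group structure: %d variables, %d groups (%d penalized), latent dimension %d\n",
    x$p, length(x$groups), sum(x$penalized), x$latent_dim))
  ov <- x$latent_dim - x$p
  if (ov > 0) cat(sprintf("  overlap: %d duplicated latent coordinates\n", ov))
  invisible(x)
}

#' Expand latent coefficients to the variable scale
#'
#' Computes `beta = A %*% gamma`, summing the latent contributions of every
#' group containing each variable.
#'
#' @param gs a [group_structure()].
#' @param gamma numeric vector of length `gs$latent_dim`.
#' @return numeric vector of length `gs$p`.
#' @export
expand_coefficients <- function(gs, gamma) {
  stopifnot(inherits(gs, "group_structure"))
  if (length(gamma) != gs$latent_dim) {
    stop(sprintf("`gamma` has length %d; expected latent dimension %d",
                 length(gamma), gs$latent_dim), call. = FALSE)
  }
  as.vector(gs$A %*% gamma)
}

#' Collapse a variable-scale vector to the latent scale
#'
#' Computes the adjoint map `t(A) %*% v`; the block for group `g` is the
#' restriction of `v` to the indices in `g`.  Used to pull gradients of the
#' loss back to the latent coordinates.
#'
#' @param gs a [group_structure()].
#' @param v numeric vector of length `gs$p`.
#' @return numeric vector of length `gs$latent_dim`.
#' @export
collapse_vector <- function(gs, v) {
  stopifnot(inherits(gs, "group_structure"))
  if (length(v) != gs$p) {
    stop(sprintf("`v` has length %d; expected %d variables",
                 length(v), gs$p), call. = FALSE)
  }
  as.vector(Matrix::crossprod(gs$A, v))
}

#' Per-group penalty weights
#'
#' Builds the penalty specification with the default size-proportional
#' weights: `lambda_g = lambda * sqrt(|g|)` for penalized groups and 0 for
#' unpenalized singleton groups.
#'
#' @param gs a [group_structure()].
#' @param lambda nonnegative global regularization parameter.
#' @param unpenalized optional integer vector of additional variable
#'   indices to exclude from regularization; if any of them are not already
#'   zero-weight singletons in `gs`, the group structure is rebuilt
#'   accordingly and returned in the result.
#' @return an object of class `"penalty_spec"` with elements `lambda`,
#'   `weights` (one per group of `gs`) and `gs` (the group structure the
#'   weights refer to; use this one downstream).
#' @export
group_weights <- function(gs, lambda, unpenalized = integer()) {
  stopifnot(inherits(gs, "group_structure"))
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0) {
    stop("`lambda` must be a single nonnegative number", call. = FALSE)
  }
  unpenalized <- .check_indices(unpenalized, gs$p, "unpenalized")
  already <- unlist(gs$groups[!gs$penalized], use.names = FALSE)
  extra <- setdiff(unpenalized, already)
  if (length(extra)) {
    gs <- .gs_set_unpenalized(gs, union(already, unpenalized))
  }
  weights <- ifelse(gs$penalized, lambda * sqrt(gs$sizes), 0)
  structure(list(lambda = lambda, weights = weights, gs = gs),
            class = "penalty_spec")
}

# Rebuild a group structure with a new unpenalized set, preserving the
# penalized user groups.
.gs_set_unpenalized <- function(gs, unpenalized) {
  pen_groups <- gs$groups[gs$penalized]
  m <- data.frame(
    variable = unlist(pen_groups, use.names = FALSE),
    group = rep.int(names(pen_groups), lengths(pen_groups)),
    stringsAsFactors = FALSE)
  group_structure(m, gs$p, unpenalized = unpenalized)
}

# Euclidean norm of each latent block; fast path for equal-sized blocks
# (the latent coordinates of a group are contiguous by construction).
.block_norms <- function(gs, x) {
  s <- gs$sizes
  if (length(s) > 1L && all(s == s[1L])) {
    return(sqrt(.colSums(x * x, s[1L], length(s))))
  }
  sqrt(drop(rowsum(x * x, gs$block, reorder = FALSE)))
}
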