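# Internal helpers: seeded RNG scoping, validation, connected components.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards.  All stochastic entry points route
# through this so that pipelines are reproducible stage by stage.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  expr
}

# Derive a child seed from a parent seed and a stage offset, kept < 2^31.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483587)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_matrix_image <- function(img, name = "img") {
  if (is.list(img) && !is.null(img$intensity)) img <- img$intensity
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L)
    stop_field(name, "must be a non-empty numeric matrix")
  if (!all(is.finite(img))) stop_field(name, "contains non-finite values")
  img
}

match_lesion_class <- function(lesion_class) {
  cls <- toupper(as.character(lesion_class))
  if (length(cls) != 1L || !cls %in% LESION_CLASSES)
    stop(sprintf("unknown lesion class '%s' (expected one of %s)",
                 lesion_class, paste(LESION_CLASSES, collapse = ", ")),
         call. = FALSE)
  cls
}

# 4-connected component labelling of a logical matrix by row-run merging
# with union-find.  Returns a list of components, each an integer matrix of
# (row, col) pixel coordinates.  Plenty fast at B-scan scale because the
# number of runs, not pixels, drives the cost.
label_components <- function(binmask) {
  stopifnot(is.logical(binmask) || is.numeric(binmask))
  binmask <- binmask != 0
  H <- nrow(binmask); W <- ncol(binmask)
  runs <- list()  # each: c(row, col_start, col_end, label)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  prev_runs <- integer(0)  # indices of runs on the previous row
  for (r in seq_len(H)) {
    rowv <- binmask[r, ]
    if (!any(rowv)) { prev_runs <- integer(0); next }
    rl <- rle(rowv)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
    cur <- integer(0)
    for (k in which(rl$values)) {
      idx <- length(runs) + 1L
      parent[idx] <- idx
      runs[[idx]] <- c(r, starts[k], ends[k])
      for (p in prev_runs) {
        pr <- runs[[p]]
        if (pr[2] <= ends[k] && pr[3] >= starts[k]) {  # column overlap
          ra <- find(idx); rb <- find(p)
          if (ra != rb) parent[ra] <- rb
        }
      }
      cur <- c(cur, idx)
    }
    prev_runs <- cur
  }
  if (!length(runs)) return(list())
  roots <- vapply(seq_along(runs), find, integer(1))
  out <- list()
  for (g in split(seq_along(runs), roots)) {
    px <- do.call(rbind, lapply(g, function(i) {
      rn <- runs[[i]]
      cbind(row = rep.int(rn[1], rn[3] - rn[2] + 1L), col = rn[2]:rn[3])
    }))
    out[[length(out) + 1L]] <- px
  }
  out
}
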