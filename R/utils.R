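#' @keywords internal
"_PACKAGE"

## Shared low-level helpers: connectivity-aware component labeling,
## natural filename ordering, and small validation utilities.

#' Label connected components of a binary 2D mask or 3D volume
#'
#' Foreground pixels/voxels are grouped into connected components under the
#' requested neighbourhood. Components are relabelled consecutively `1..k` in
#' order of their smallest linear index, so labels are deterministic.
#'
#' @param mask Logical (or 0/1 numeric) matrix, or 3D array for volumes.
#' @param connectivity For matrices: 4 or 8. For 3D arrays: 6, 18 or 26.
#' @return Integer array of the same shape; 0 marks background.
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
#' max(label_components(m, connectivity = 8)) # diagonal pair: 1 component
#' @export
label_components <- function(mask, connectivity = if (length(dim(mask)) == 3) 26L else 8L) {
  dm <- dim(mask)
  if (is.null(dm) || !(length(dm) %in% c(2L, 3L))) {
    stop("`mask` must be a 2D matrix or a 3D array")
  }
  mask <- mask != 0
  out <- array(0L, dm)
  fg <- which(mask)
  if (length(fg) == 0L) return(out)

  offsets <- connectivity_offsets(length(dm), connectivity)
  idx <- arrayInd(fg, dm)
  # map linear index -> vertex id (dense over foreground only)
  vid <- integer(prod(dm))
  vid[fg] <- seq_along(fg)

  edges_from <- integer(0)
  edges_to <- integer(0)
  for (k in seq_len(nrow(offsets))) {
    shifted <- idx
    for (d in seq_len(ncol(offsets))) shifted[, d] <- idx[, d] + offsets[k, d]
    ok <- rep(TRUE, nrow(shifted))
    for (d in seq_len(ncol(offsets))) {
      ok <- ok & shifted[, d] >= 1L & shifted[, d] <= dm[d]
    }
    if (!any(ok)) next
    lin <- linear_index(shifted[ok, , drop = FALSE], dm)
    hit <- mask[lin]
    if (!any(hit)) next
    edges_from <- c(edges_from, vid[fg[ok][hit]])
    edges_to <- c(edges_to, vid[lin[hit]])
  }

  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges_from)) {
    g <- igraph::add_edges(g, rbind(edges_from, edges_to))
  }
  comp <- igraph::components(g)$membership
  # relabel by first occurrence (fg is sorted by linear index)
  relab <- integer(max(comp))
  nxt <- 1L
  for (i in seq_along(fg)) {
    if (relab[comp[i]] == 0L) {
      relab[comp[i]] <- nxt
      nxt <- nxt + 1L
    }
  }
  out[fg] <- relab[comp]
  out
}

# Half-neighbourhood offsets (forward only; undirected edges cover the rest).
connectivity_offsets <- function(ndim, connectivity) {
  if (ndim == 2L) {
    if (connectivity == 4) {
      matrix(c(1L, 0L, 0L, 1L), ncol = 2, byrow = TRUE)
    } else if (connectivity == 8) {
      matrix(c(1L, 0L, 0L, 1L, 1L, 1L, 1L, -1L), ncol = 2, byrow = TRUE)
    } else stop("2D connectivity must be 4 or 8")
  } else {
    full <- as.matrix(expand.grid(dr = -1:1, dc = -1:1, dz = -1:1))
    full <- full[rowSums(full != 0) > 0, , drop = FALSE]
    deg <- rowSums(abs(full))
    keep <- switch(as.character(connectivity),
      "6" = deg == 1, "18" = deg <= 2, "26" = deg <= 3,
      stop("3D connectivity must be 6, 18 or 26"))
    full <- full[keep, , drop = FALSE]
    # forward half: first nonzero coordinate positive
    half <- apply(full, 1, function(o) {
      nz <- o[o != 0]
      nz[1] > 0
    })
    storage.mode(full) <- "integer"
    full[half, , drop = FALSE]
  }
}

linear_index <- function(ind, dm) {
  lin <- ind[, 1]
  mult <- 1
  for (d in seq_len(length(dm) - 1)) {
    mult <- mult * dm[d]
    lin <- lin + (ind[, d + 1] - 1L) * mult
  }
  lin
}

#' Natural (numeric-aware) sort of file names
#'
#' Orders `img2` before `img10`, independent of zero-padding style, so slice
#' order survives inconsistent tomography export naming.
#'
#' @param x Character vector of file names.
#' @return `x`, reordered.
#' @export
natural_sort <- function(x) {
  pad <- function(s) {
    m <- gregexpr("\\d+", s)
    regmatches(s, m) <- lapply(regmatches(s, m), function(runs) {
      sprintf("%020d", as.numeric(runs))
    })
    s
  }
  x[order(pad(tolower(x)), x)]
}

# Pixel counts per label of a label image; names are the labels.
label_sizes <- function(lbl) {
  tab <- tabulate(lbl[lbl > 0L])
  stats::setNames(tab, seq_along(tab))
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive number", name))
  }
  invisible(x)
}

# Separable 2D convolution with replicate padding; `kr`, `kc` are the row/col
# 1D kernels (odd lengths). Used by the Canny gradient stage.
conv_separable <- function(img, kr, kc) {
  conv_along_rows <- function(m, k) {
    h <- (length(k) - 1L) / 2L
    n <- nrow(m)
    padded <- rbind(m[rep(1L, h), , drop = FALSE], m, m[rep(n, h), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * padded[i:(i + n - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_along_rows(t(conv_along_rows(img, kr)), kc))
}
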