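# Intracranial structure extraction and the boundary-intensity LoG edge
# detector.

# Connected-component labelling of a logical mask.
# EBImage::bwlabel is 4-connected; the 8-connected case goes through igraph.
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (connectivity == 4) return(EBImage::bwlabel(m))
  nr <- nrow(m); nc <- ncol(m)
  idx <- which(m > 0)
  if (length(idx) == 0) return(matrix(0L, nr, nc))
  inside <- matrix(FALSE, nr, nc); inside[idx] <- TRUE
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  edges <- NULL
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rows + d[1]; c2 <- cols + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- inside[j]
    edges <- rbind(edges, cbind(idx[ok][keep], j[keep]))
  }
  vmap <- match(seq_len(nr * nc), idx)
  g <- igraph::graph_from_edgelist(
    cbind(vmap[edges[, 1]], vmap[edges[, 2]]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out <- matrix(0L, nr, nc)
  out[idx] <- comp
  out
}

largest_component <- function(labelled) {
  if (max(labelled) == 0) return(labelled > 0)
  sizes <- tabulate(labelled[labelled > 0])
  labelled == which.max(sizes)
}

#' Extract the intracranial region of a CT slice
#'
#' Removes the skull and everything outside it: threshold bone
#' (HU >= `bone_hu`), keep the largest connected bone component, fill its
#' interior, erode by one pixel and exclude the bone itself. The result never
#' intersects the bone mask. If no bone is found the whole image is returned
#' as the mask, with a warning, so downstream steps still run on skull-less
#' inputs.
#'
#' @param slice_hu 2-D matrix of HU-calibrated values.
#' @param bone_hu bone threshold in HU (default 300).
#' @return Logical matrix marking intracranial pixels.
#' @export
extract_intracranial <- function(slice_hu, bone_hu = 300) {
  stopifnot(is.matrix(slice_hu))
  bone <- slice_hu >= bone_hu
  if (!any(bone)) {
    warning("no bone found above ", bone_hu, " HU; returning whole-image mask",
            call. = FALSE)
    return(matrix(TRUE, nrow(slice_hu), ncol(slice_hu)))
  }
  main_bone <- largest_component(label_components(bone, 8))
  filled <- EBImage::fillHull(matrix(as.numeric(main_bone), nrow(slice_hu))) > 0
  eroded <- EBImage::erode(matrix(as.numeric(filled), nrow(slice_hu)),
                           EBImage::makeBrush(3, "box")) > 0
  eroded & !bone
}

# Laplacian-of-Gaussian kernel, zero-sum normalized.
log_kernel <- function(sigma) {
  h <- max(2L, ceiling(3 * sigma))
  g <- expand.grid(x = -h:h, y = -h:h)
  r2 <- g$x^2 + g$y^2
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k <- k - mean(k)
  matrix(k, 2L * h + 1L)
}

# Otsu threshold of a numeric vector (256-bin histogram).
otsu_threshold <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0 || diff(range(v)) == 0) return(min(v, 0))
  br <- seq(min(v), max(v), length.out = 257)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = 256)
  w <- h / sum(h)
  mids <- (br[-1] + br[-257]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[256]
  bc <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bc[!is.finite(bc)] <- 0
  mids[which.max(bc)]
}

#' Laplacian-of-Gaussian edge detection with boundary intensity filtering
#'
#' LoG-filters the image, marks zero-crossings between 4-neighbors of
#' opposite sign (the crossing is placed on the pixel with the smaller
#' absolute LoG response, giving one-pixel-wide deterministic edges), and
#' attaches to each edge pixel a boundary intensity equal to the local
#' gradient magnitude. Crossings weaker than `strength_threshold` are
#' discarded, which filters the false (low-contrast) edges that a plain LoG
#' operator keeps because it weights all zero-crossings identically.
#'
#' The edge map is invariant to adding a constant to the image, and the
#' strengths scale linearly with image contrast.
#'
#' @param image numeric matrix (any intensity scale).
#' @param sigma LoG scale in pixels (default 2).
#' @param strength_threshold minimum boundary intensity; `NULL` (default)
#'   uses Otsu's threshold over the observed strengths, `0` keeps every
#'   zero-crossing.
#' @return Object of class `"edge_map"`: list with logical `mask`, numeric
#'   `strength` (NA off the edges), and the threshold used.
#' @export
log_edge_detect <- function(image, sigma = 2, strength_threshold = NULL) {
  stopifnot(is.matrix(image))
  k <- log_kernel(sigma)
  p <- (nrow(k) - 1L) %/% 2L
  padded <- pad_mirror(image, p)
  resp <- EBImage::filter2(padded, k, boundary = "replicate")
  resp <- resp[(p + 1):(p + nrow(image)), (p + 1):(p + ncol(image))]
  # flush float residue so flat regions produce no spurious crossings
  resp[abs(resp) < 1e-10 * (1 + max(abs(image)))] <- 0

  nr <- nrow(resp); nc <- ncol(resp)
  cross <- matrix(FALSE, nr, nc)
  # vertical neighbor pairs
  a <- resp[-nr, ]; b <- resp[-1, ]
  opp <- a * b < 0
  lowa <- abs(a) <= abs(b)
  cross[-nr, ][opp & lowa] <- TRUE
  cross[-1, ][opp & !lowa] <- TRUE
  # horizontal neighbor pairs
  a <- resp[, -nc]; b <- resp[, -1]
  opp <- a * b < 0
  lowa <- abs(a) <= abs(b)
  cross[, -nc][opp & lowa] <- TRUE
  cross[, -1][opp & !lowa] <- TRUE

  # gradient magnitude by central differences (mirror borders)
  pim <- pad_mirror(image, 1L)
  gx <- (pim[2:(nr + 1), 3:(nc + 2)] - pim[2:(nr + 1), 1:nc]) / 2
  gy <- (pim[3:(nr + 2), 2:(nc + 1)] - pim[1:nr, 2:(nc + 1)]) / 2
  grad <- sqrt(gx^2 + gy^2)

  if (is.null(strength_threshold))
    strength_threshold <- if (any(cross)) otsu_threshold(grad[cross]) else 0
  keep <- cross & grad >= strength_threshold
  strength <- matrix(NA_real_, nr, nc)
  strength[keep] <- grad[keep]
  structure(list(mask = keep, strength = strength,
                 threshold = strength_threshold, sigma = sigma),
            class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  cat("Edge map:", sum(x$mask), "edge pixels (sigma =", x$sigma,
      ", strength threshold =", signif(x$threshold, 4), ")\n")
  invisible(x)
}
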