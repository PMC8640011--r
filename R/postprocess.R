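# Post-processing of predicted masks: keep only the largest contour.

# 8-connectivity labeling: EBImage::bwlabel is 4-connectivity, so labels
# touching diagonally are merged with a small union-find afterwards.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),  # down-right
    cbind(as.vector(lab[-1L, -nc]), as.vector(lab[-nr, -1L]))   # up-right
  )
  pairs <- pairs[pairs[, 1L] > 0 & pairs[, 2L] > 0 & pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1L]); b <- find(pairs[r, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1L))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Keep only the largest connected component of a binary mask
#'
#' Cleanup of predicted masks: all foreground contours are extracted and
#' only the one enclosing the largest (hole-filled) area survives,
#' discarding outlying fragments. Components are 8-connected; holes inside
#' the winning contour are filled. Area ties are broken by the higher mean
#' soft-prediction score (when `soft` is supplied), then by the lowest
#' raster index. An all-zero mask passes through unchanged, flagged with
#' `attr(, "empty_prediction")`.
#'
#' @param mask binary matrix.
#' @param soft optional soft prediction map used only for tie-breaking.
#' @return binary matrix of the filled largest component.
#' @examples
#' m <- matrix(0, 16, 16); m[4:12, 4:12] <- 1; m[15, 15] <- 1
#' sum(largest_component_mask(m))  # the 9x9 block only, speckle removed
#' @export
largest_component_mask <- function(mask, soft = NULL) {
  check_mask(mask)
  if (sum(mask) == 0) {
    attr(mask, "empty_prediction") <- TRUE
    return(mask)
  }
  lab <- label_components8(mask)
  filled <- EBImage::fillHull(lab)
  nlab <- max(lab)
  areas <- tabulate(filled[filled > 0], nbins = nlab)
  best <- which(areas == max(areas))
  if (length(best) > 1L && !is.null(soft)) {
    sc <- vapply(best, function(k) mean(soft[filled == k]), numeric(1L))
    best <- best[sc == max(sc)]
  }
  if (length(best) > 1L) {
    first_idx <- vapply(best, function(k) which(filled == k)[1L], integer(1L))
    best <- best[which.min(first_idx)]
  }
  out <- (filled == best[1L]) * 1
  attr(out, "empty_prediction") <- FALSE
  out
}

#' Extract the outer contour of the largest component
#'
#' Ordered closed boundary (8-connected tracing) of the largest filled
#' component, suitable for overlay rendering or shoelace area computation.
#'
#' @param mask binary matrix with at least one foreground pixel.
#' @return integer matrix with columns `row`, `col` (1-indexed boundary
#'   pixel coordinates, in traversal order).
#' @export
extract_contour <- function(mask) {
  check_mask(mask)
  if (sum(mask) == 0) stopf("mask has no foreground pixels")
  comp <- largest_component_mask(mask)
  oc <- EBImage::ocontour(comp)[[1L]]
  cbind(row = oc[, 1L] + 1L, col = oc[, 2L] + 1L)
}

#' Write a contour to CSV
#'
#' @param contour matrix from [extract_contour()].
#' @param path output CSV path.
#' @export
write_contour <- function(contour, path) {
  write.csv(as.data.frame(contour), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
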