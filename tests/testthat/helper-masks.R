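# Erode a logical mask by Chebyshev radius r (drop pixels within r of the
# boundary), clamping at the image edge.
erode_mask <- function(mask, r = 2L) {
  H <- nrow(mask); W <- ncol(mask)
  out <- mask
  for (dr in -r:r) for (dc in -r:r) {
    ri <- pmin(pmax(row(mask) + dr, 1L), H)
    ci <- pmin(pmax(col(mask) + dc, 1L), W)
    out <- out & matrix(mask[cbind(as.vector(ri), as.vector(ci))], H, W)
  }
  out
}

# TRUE where the whole (2r+1)^2 neighbourhood shares one region label.
label_interior <- function(labels, r = 2L) {
  H <- nrow(labels); W <- ncol(labels)
  out <- matrix(TRUE, H, W)
  for (dr in -r:r) for (dc in -r:r) {
    ri <- pmin(pmax(row(labels) + dr, 1L), H)
    ci <- pmin(pmax(col(labels) + dc, 1L), W)
    out <- out & matrix(labels[cbind(as.vector(ri), as.vector(ci))] ==
                          as.vector(labels), H, W)
  }
  out
}
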