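# Outer-boundary extraction for a single connected component.
#
# Moore-neighbour tracing over the 8-neighbourhood, starting from the
# first member pixel in column-major scan order, with the classic
# backtracking rule; terminates on return to the start pixel.  Good for
# the compact blobs this package segments; self-touching figure-eight
# shapes may close early, which only shortens the reported contour.

# clockwise neighbour offsets starting from W: (dr, dc)
.moore_off <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1,
                       0, 1, 1, 1, 1, 0, 1, -1),
                     ncol = 2, byrow = TRUE)

trace_contour <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(NULL)
  r0 <- ((idx[1] - 1L) %% nr) + 1L
  c0 <- ((idx[1] - 1L) %/% nr) + 1L
  out1 <- matrix(c(c0 - 1L, r0 - 1L), 1, 2,
                 dimnames = list(NULL, c("x", "y")))
  if (length(idx) == 1L) return(out1)
  inside <- function(r, c) {
    r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c]
  }
  pts <- matrix(NA_integer_, 4L * length(idx) + 8L, 2L)
  np <- 0L
  r <- r0; c <- c0
  dir <- 1L  # search starts at the W neighbour
  repeat {
    np <- np + 1L
    pts[np, ] <- c(r, c)
    found <- FALSE
    for (k in 0:7) {
      d <- ((dir - 1L + k) %% 8L) + 1L
      rr <- r + .moore_off[d, 1L]
      cc <- c + .moore_off[d, 2L]
      if (inside(rr, cc)) {
        # restart the next search one position clockwise of the
        # backtrack direction relative to the new pixel
        dir <- ((d + 5L) %% 8L) + 1L
        r <- rr; c <- cc
        found <- TRUE
        break
      }
    }
    if (!found) break                      # isolated pixel
    if (r == r0 && c == c0 && np > 2L) break
  }
  pts <- pts[seq_len(np), , drop = FALSE]
  cbind(x = pts[, 2L] - 1L, y = pts[, 1L] - 1L)
}

# Perimeter as the closed boundary-chain length through pixel centers
# (axis steps 1, diagonal steps sqrt(2)).  Single-pixel components get
# the unit-square boundary length 4.
contour_perimeter <- function(contour) {
  if (is.null(contour) || nrow(contour) == 1L) return(4)
  closed <- rbind(contour, contour[1L, , drop = FALSE])
  steps <- diff(closed)
  max(sum(sqrt(rowSums(steps^2))), 4)
}
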