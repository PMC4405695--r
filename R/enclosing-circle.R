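## Minimal enclosing circle of a 2-D point set, Welzl's algorithm in its
## iterative move-to-front form (expected linear time after shuffling).
## This is the operator behind the confinement-area statistic, so it is
## exact up to floating tolerance and verified against brute-force
## enumeration over point pairs and triples in the test suite.

MEC_EPS <- 1e-10

circle_contains <- function(circ, pts) {
  dx <- pts[, 1] - circ$cx
  dy <- pts[, 2] - circ$cy
  dx * dx + dy * dy <= circ$r2 * (1 + MEC_EPS) + MEC_EPS
}

circle_from_2 <- function(a, b) {
  cx <- (a[1] + b[1]) / 2
  cy <- (a[2] + b[2]) / 2
  r2 <- ((a[1] - b[1])^2 + (a[2] - b[2])^2) / 4
  list(cx = cx, cy = cy, r2 = r2)
}

## Circumcircle of a triangle; falls back to the widest diameter circle when
## the points are (near-)collinear.
circle_from_3 <- function(a, b, c) {
  ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  scale2 <- max(abs(c(ax, ay, bx, by, cx, cy)), 1)^2
  if (abs(d) < MEC_EPS * scale2) {
    pts <- rbind(a, b, c)
    pairs <- list(c(1, 2), c(1, 3), c(2, 3))
    best <- NULL
    for (pr in pairs) {
      circ <- circle_from_2(pts[pr[1], ], pts[pr[2], ])
      if (all(circle_contains(circ, pts)) &&
          (is.null(best) || circ$r2 < best$r2)) best <- circ
    }
    return(best)
  }
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(cx = ux, cy = uy, r2 = (ux - ax)^2 + (uy - ay)^2)
}

#' Minimal enclosing circle
#'
#' Smallest circle containing every point of a 2-D set; the circle drawn
#' around a confined vesicle track to summarize the area it explored.
#'
#' @param xy numeric matrix or data frame with two columns (x, y).
#' @param shuffle_seed seed for the internal point shuffle; the result is
#'   the same circle for any seed, this only fixes the iteration order.
#' @return List with `center` (length-2), `radius`, and `area`.
#' @export
min_enclosing_circle <- function(xy, shuffle_seed = 1L) {
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  if (ncol(xy) != 2) stop("'xy' must have two columns", call. = FALSE)
  if (!all(is.finite(xy))) stop("points must be finite", call. = FALSE)
  xy <- unique(xy)
  n <- nrow(xy)
  if (n == 0) stop("no points supplied", call. = FALSE)
  if (n == 1) {
    circ <- list(cx = xy[1, 1], cy = xy[1, 2], r2 = 0)
  } else {
    idx <- with_seed(shuffle_seed, sample.int(n))
    xy <- xy[idx, , drop = FALSE]
    circ <- list(cx = xy[1, 1], cy = xy[1, 2], r2 = 0)
    for (i in seq_len(n)) {
      pi_ <- xy[i, ]
      if (circle_contains(circ, rbind(pi_))) next
      circ <- list(cx = pi_[1], cy = pi_[2], r2 = 0)
      for (j in seq_len(i - 1)) {
        pj <- xy[j, ]
        if (circle_contains(circ, rbind(pj))) next
        circ <- circle_from_2(pi_, pj)
        for (k in seq_len(j - 1)) {
          pk <- xy[k, ]
          if (circle_contains(circ, rbind(pk))) next
          circ <- circle_from_3(pi_, pj, pk)
        }
      }
    }
  }
  r <- sqrt(circ$r2)
  list(center = c(circ$cx, circ$cy), radius = r, area = pi * r^2)
}

#' Brute-force minimal enclosing circle (independent oracle)
#'
#' Enumerates every diameter circle over point pairs and every circumcircle
#' over point triples, keeping the smallest circle that contains the whole
#' set. Exact for any point set (the minimal circle is determined by 2 or 3
#' points) but O(n^4); intended as the independent check of
#' [min_enclosing_circle()] on small sets.
#'
#' @param xy numeric matrix with two columns (x, y), at most a few dozen rows.
#' @return List with `center`, `radius`, `area`.
#' @export
mec_brute_force <- function(xy) {
  xy <- unique(as.matrix(xy))
  storage.mode(xy) <- "double"
  n <- nrow(xy)
  if (n == 1)
    return(list(center = xy[1, ], radius = 0, area = 0))
  prs <- utils::combn(n, 2)
  cx <- (xy[prs[1, ], 1] + xy[prs[2, ], 1]) / 2
  cy <- (xy[prs[1, ], 2] + xy[prs[2, ], 2]) / 2
  r2 <- ((xy[prs[1, ], 1] - xy[prs[2, ], 1])^2 +
           (xy[prs[1, ], 2] - xy[prs[2, ], 2])^2) / 4
  if (n >= 3) {
    tri <- utils::combn(n, 3)
    ax <- xy[tri[1, ], 1]; ay <- xy[tri[1, ], 2]
    bx <- xy[tri[2, ], 1]; by <- xy[tri[2, ], 2]
    tcx <- xy[tri[3, ], 1]; tcy <- xy[tri[3, ], 2]
    d <- 2 * (ax * (by - tcy) + bx * (tcy - ay) + tcx * (ay - by))
    ok <- abs(d) > MEC_EPS
    if (any(ok)) {
      a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- tcx^2 + tcy^2
      ux <- (a2 * (by - tcy) + b2 * (tcy - ay) + c2 * (ay - by))[ok] / d[ok]
      uy <- (a2 * (tcx - bx) + b2 * (ax - tcx) + c2 * (bx - ax))[ok] / d[ok]
      rr2 <- (ux - ax[ok])^2 + (uy - ay[ok])^2
      cx <- c(cx, ux); cy <- c(cy, uy); r2 <- c(r2, rr2)
    }
  }
  ## containment: a circle is valid if its largest point distance <= radius
  d2 <- outer(cx, xy[, 1], "-")^2 + outer(cy, xy[, 2], "-")^2
  slack <- r2 * (1 + MEC_EPS) + MEC_EPS
  valid <- apply(d2, 1, max) <= slack
  i <- which(valid)[which.min(r2[valid])]
  r <- sqrt(r2[i])
  list(center = c(cx[i], cy[i]), radius = r, area = pi * r^2)
}
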