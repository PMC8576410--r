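#' Classify diastolic activation timing into early/mid/late
#'
#' The diastolic window starts at the end of the QRS complex and is split
#' into three equal tertiles; a diastolic activation time is classified
#' by tertile membership. Tertile intervals are half-open,
#' `[start, start + w/3)` etc., with the final tertile closed at
#' `window_end` being exclusive (times are expected to be pre-wrapped
#' modulo the cycle length into the window).
#'
#' @param t Activation time(s), ms.
#' @param window_start Diastolic window start (QRS end), ms.
#' @param window_end Diastolic window end, ms (`> window_start`).
#' @return Factor with levels `early`, `mid`, `late`.
#' @export
#' @examples
#' classify_diastolic_phase(c(100, 250, 399), 100, 400)
classify_diastolic_phase <- function(t, window_start, window_end) {
  if (window_start >= window_end) stop("window_start must be < window_end")
  if (any(!is.finite(t))) stop("non-finite activation time")
  if (any(t < window_start | t >= window_end))
    stop("activation time outside the diastolic window [",
         window_start, ", ", window_end, ")")
  w <- (window_end - window_start) / 3
  idx <- pmin(floor((t - window_start) / w), 2)
  factor(c("early", "mid", "late")[idx + 1],
         levels = c("early", "mid", "late"))
}

#' Detect lines of conduction block in an activation map
#'
#' Operationalises the mapping criterion that conduction block separates
#' adjacent activation points by more than `dt_block` (15 ms): an
#' adjacency graph is built over mapping points within
#' `neighbor_radius`; edges whose endpoint activation times differ by
#' more than `dt_block` are block-crossing edges; the midpoints of those
#' edges trace the block boundary and are merged into connected chains
#' (components of the midpoint proximity graph). Each chain is ordered
#' along its principal axis and lightly smoothed before its arc length is
#' measured; the total block extent is the sum of chain lengths.
#'
#' @param points Tibble/data frame with `x, y, z, time_ms` (>= 10 rows).
#' @param dt_block Activation-time difference defining block, ms.
#' @param neighbor_radius Point adjacency radius, mm (mapping-point
#'   density scale).
#' @param bin_mm Bin width for the centreline estimate along each
#'   chain's principal axis (default `neighbor_radius / 2.5`): midpoints
#'   falling in a bin are averaged, which suppresses the lateral scatter
#'   of crossing-edge midpoints around the true line.
#' @param direction_filter If `TRUE`, a chain is kept only when the mean
#'   activation-time gradients fitted on its two sides differ in
#'   direction by more than 90 degrees (opposing wavefronts), dropping
#'   pseudo-boundaries within a single wavefront.
#' @return List: `block_lines` (list of ordered polyline matrices),
#'   `total_length_mm`, `n_regions`, `block_edges` (tibble of crossing
#'   pairs).
#' @export
detect_block_lines <- function(points, dt_block = 15, neighbor_radius = 5,
                               bin_mm = neighbor_radius / 2.5,
                               direction_filter = FALSE) {
  pts <- as.matrix(points[, c("x", "y", "z")])
  tm <- points$time_ms
  if (nrow(pts) < 10L) stop("need at least 10 mapping points")
  if (max(stats::dist(pts[seq_len(min(200L, nrow(pts))), ])) < 1e-9)
    stop("degenerate map: all points coincident")
  # adjacency pairs within radius (upper triangle, chunked)
  n <- nrow(pts)
  pairs <- list(); np <- 0L
  chunk <- 256L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(rowSums(pts[s:e, , drop = FALSE]^2), rowSums(pts^2), `+`) -
      2 * pts[s:e, , drop = FALSE] %*% t(pts)
    idx <- which(d2 <= neighbor_radius^2, arr.ind = TRUE)
    idx[, 1] <- idx[, 1] + s - 1L
    keep <- idx[, 1] < idx[, 2]
    if (any(keep)) { np <- np + 1L; pairs[[np]] <- idx[keep, , drop = FALSE] }
  }
  pairs <- if (np) do.call(rbind, pairs) else matrix(integer(0), 0, 2)
  dt <- abs(tm[pairs[, 1]] - tm[pairs[, 2]])
  cross <- pairs[dt > dt_block, , drop = FALSE]
  if (!nrow(cross))
    return(list(block_lines = list(), total_length_mm = 0, n_regions = 0L,
                block_edges = tibble::tibble(i = integer(0), j = integer(0),
                                             dt_ms = numeric(0))))
  mids <- (pts[cross[, 1], , drop = FALSE] + pts[cross[, 2], , drop = FALSE]) / 2
  # merge midpoints into chains: components of their proximity graph
  m <- nrow(mids)
  md2 <- outer(rowSums(mids^2), rowSums(mids^2), `+`) - 2 * mids %*% t(mids)
  adj <- which(md2 <= neighbor_radius^2, arr.ind = TRUE)
  adj <- adj[adj[, 1] < adj[, 2], , drop = FALSE]
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (nrow(adj)) g <- igraph::add_edges(g, t(adj))
  comp <- igraph::components(g)$membership
  chains <- list(); total <- 0
  for (cid in sort(unique(comp))) {
    sel <- comp == cid
    mp <- mids[sel, , drop = FALSE]
    ce <- cross[sel, , drop = FALSE]
    if (direction_filter && !.opposing_fronts(pts, tm, ce)) next
    mp <- unique(round(mp, 6))
    if (nrow(mp) < 2L) { chains[[length(chains) + 1L]] <- mp; next }
    ctr <- colMeans(mp)
    ax <- svd(sweep(mp, 2L, ctr))$v[, 1]
    proj <- as.numeric(sweep(mp, 2L, ctr) %*% ax)
    # centreline: average midpoints within bins along the principal axis
    br <- range(proj)
    nb <- max(2L, ceiling(diff(br) / bin_mm))
    bin <- pmin(pmax(findInterval(proj, seq(br[1], br[2], length.out = nb + 1L),
                                  rightmost.closed = TRUE), 1L), nb)
    cl <- rowsum(mp, bin) / as.vector(table(bin))
    cl <- cl[order(sort(unique(bin))), , drop = FALSE]
    seg <- sqrt(rowSums(diff(cl)^2))
    total <- total + sum(seg)
    chains[[length(chains) + 1L]] <- cl
  }
  list(block_lines = chains, total_length_mm = total,
       n_regions = length(chains),
       block_edges = tibble::tibble(i = cross[, 1], j = cross[, 2],
                                    dt_ms = dt[dt > dt_block]))
}

# Do the two sides of a chain carry opposing wavefronts? Fits a linear
# activation-time gradient on the early and late endpoints of the
# chain's crossing edges; angle > 90 degrees means opposing.
.opposing_fronts <- function(pts, tm, cross_edges) {
  early <- ifelse(tm[cross_edges[, 1]] <= tm[cross_edges[, 2]],
                  cross_edges[, 1], cross_edges[, 2])
  late <- ifelse(tm[cross_edges[, 1]] <= tm[cross_edges[, 2]],
                 cross_edges[, 2], cross_edges[, 1])
  gfit <- function(ids) {
    ids <- unique(ids)
    if (length(ids) < 4L) return(NULL)
    X <- cbind(1, pts[ids, , drop = FALSE])
    qr_ <- qr(X)
    if (qr_$rank < 3L) return(NULL)
    stats::coef(stats::lm.fit(X, tm[ids]))[2:4]
  }
  g1 <- gfit(early); g2 <- gfit(late)
  if (is.null(g1) || is.null(g2)) return(TRUE)   # too few points to judge
  g1[is.na(g1)] <- 0; g2[is.na(g2)] <- 0
  n1 <- sqrt(sum(g1^2)); n2 <- sqrt(sum(g2^2))
  if (n1 < 1e-9 || n2 < 1e-9) return(TRUE)
  sum(g1 * g2) / (n1 * n2) < 0
}

#' Tabulate conduction-block extent per rhythm
#'
#' Runs [detect_block_lines()] on one activation map per rhythm (e.g.
#' RV pacing at 500 ms / 300 ms and mapped VT) and tabulates the total
#' block extent, ready for paired comparison.
#'
#' @param maps Named list of activation-point tables (one or more per
#'   rhythm label; names give the rhythm).
#' @param dt_block,neighbor_radius Passed to [detect_block_lines()].
#' @return Tibble: `rhythm`, `map`, `total_block_mm`, `n_regions`.
#' @export
block_extent_by_rhythm <- function(maps, dt_block = 15, neighbor_radius = 5) {
  stopifnot(length(maps) >= 1L, !is.null(names(maps)))
  purrr::imap_dfr(maps, function(mp, nm) {
    bl <- detect_block_lines(mp, dt_block, neighbor_radius)
    tibble::tibble(rhythm = nm, total_block_mm = bl$total_length_mm,
                   n_regions = bl$n_regions)
  })
}
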