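#' Region-to-region connection-strength matrix from streamlines
#'
#' Counts streamline connections between parcellation labels.  In
#' `"endpoint"` mode each streamline increments the cell indexed by the
#' labels of its two endpoints (symmetrised); in `"passthrough"` mode each
#' streamline increments every pair of distinct labels it visits, once per
#' pair, plus its single-label diagonal cell when it stays inside one
#' region.  Endpoints falling just outside the labelled support are snapped
#' to the nearest label within one voxel; streamlines whose endpoints
#' cannot be assigned are dropped and counted in the QC attribute.
#'
#' @param streamlines a `streamline_set` (world mm coordinates).
#' @param parcellation a `parcellation` on the same grid.
#' @param mode `"endpoint"` (default) or `"passthrough"`.
#' @param normalization `"raw"` counts (default) or `"volume"`
#'   (cell (i,j) divided by `sqrt(Vi * Vj)` with V the label voxel counts).
#' @param voxel_size voxel edge length of the parcellation grid, mm.
#' @return object of class `connection_matrix`: `matrix` (square, labelled),
#'   `mode`, `normalization`, `label_table`, and attribute `n_dropped`.
#' @export
connection_matrix <- function(streamlines, parcellation,
                              mode = c("endpoint", "passthrough"),
                              normalization = c("raw", "volume"),
                              voxel_size = streamlines$voxel_size) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  stopifnot(inherits(streamlines, "streamline_set"),
            inherits(parcellation, "parcellation"))
  lab <- parcellation$labels
  if (sum(lab != 0L) == 0L) stop("empty parcellation")
  d <- dim(lab)
  codes <- parcellation$table$code
  k <- length(codes)
  M <- matrix(0, k, k)
  nm <- if (all(!is.na(parcellation$table$part)) &&
            all(!is.na(parcellation$table$zone)))
    paste(parcellation$table$part, parcellation$table$zone, sep = ".")
  else if (all(!is.na(parcellation$table$zone))) parcellation$table$zone
  else parcellation$table$part
  dimnames(M) <- list(nm, nm)
  code_row <- match(seq_len(max(codes)), codes)
  label_at <- function(p) {
    # p: world mm; nearest-voxel lookup with 1-voxel snap for endpoints
    v <- round(p / voxel_size) + 1
    if (any(v < 1) || any(v > d)) v <- pmin(pmax(v, 1), d)
    l <- lab[v[1], v[2], v[3]]
    l
  }
  snap_label <- function(p) {
    l <- label_at(p)
    if (l != 0L) return(l)
    v0 <- round(p / voxel_size) + 1
    best <- 0L; bestd <- Inf
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      v <- v0 + c(dx, dy, dz)
      if (any(v < 1) || any(v > d)) next
      l <- lab[v[1], v[2], v[3]]
      if (l == 0L) next
      dist <- sqrt(sum((((v - 1) * voxel_size) - p)^2)) / voxel_size
      if (dist <= 1 && dist < bestd) { best <- l; bestd <- dist }
    }
    best
  }
  n_dropped <- 0L
  for (m in streamlines$streamlines) {
    if (mode == "endpoint") {
      a <- snap_label(m[1, ])
      b <- snap_label(m[nrow(m), ])
      if (a == 0L || b == 0L) { n_dropped <- n_dropped + 1L; next }
      i <- code_row[a]; j <- code_row[b]
      M[i, j] <- M[i, j] + 1
      if (i != j) M[j, i] <- M[j, i] + 1
    } else {
      ls <- unique(apply(m, 1, label_at))
      ls <- ls[ls != 0L]
      if (length(ls) == 0L) { n_dropped <- n_dropped + 1L; next }
      rows <- code_row[ls]
      if (length(rows) == 1L) {
        M[rows, rows] <- M[rows, rows] + 1
      } else {
        pr <- utils::combn(rows, 2)
        for (c2 in seq_len(ncol(pr))) {
          i <- pr[1, c2]; j <- pr[2, c2]
          M[i, j] <- M[i, j] + 1
          M[j, i] <- M[j, i] + 1
        }
      }
    }
  }
  if (normalization == "volume") {
    vol <- vapply(codes, function(cd) sum(lab == cd), 1.0)
    vol[vol == 0] <- NA
    M <- M / sqrt(outer(vol, vol))
    M[is.na(M)] <- 0
  }
  structure(list(matrix = M, mode = mode, normalization = normalization,
                 label_table = parcellation$table, n_dropped = n_dropped),
            class = "connection_matrix")
}

#' @export
print.connection_matrix <- function(x, ...) {
  cat(sprintf("<connection_matrix> %d x %d, mode=%s, normalization=%s, dropped=%d\n",
              nrow(x$matrix), ncol(x$matrix), x$mode, x$normalization,
              x$n_dropped))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Render a connection matrix as a heatmap image plus a text table
#'
#' Writes a PNG heatmap with row/column labels in parcellation-code order —
#' for the 9-region parcellation that is (anterior, body, posterior) x
#' (W-W, R-W, R-R) — a matching comma-separated table, and a JSON sidecar
#' recording the label order.  The colour scale is linear from 0 to the
#' matrix maximum.
#'
#' @param cmatrix a `connection_matrix`.
#' @param path output PNG path; the table goes to `<path>.csv` and the
#'   sidecar to `<path>.json` (extension replaced).
#' @return invisibly, the written paths.
#' @export
render_heatmap <- function(cmatrix, path) {
  stopifnot(inherits(cmatrix, "connection_matrix"))
  M <- cmatrix$matrix
  base <- sub("\\.png$", "", path)
  csv_path <- paste0(base, ".csv")
  json_path <- paste0(base, ".json")
  utils::write.table(M, csv_path, sep = ",", col.names = NA, quote = FALSE)
  jsonlite::write_json(list(labels = colnames(M), mode = cmatrix$mode,
                            normalization = cmatrix$normalization),
                       json_path, auto_unbox = TRUE)
  k <- nrow(M)
  mx <- max(M)
  pal <- colorRampPalette(c("#000040", "#2060c0", "#40c0a0", "#f0e040",
                            "#c00000"))(256)
  grDevices::png(path, width = 640, height = 560)
  op <- par(mar = c(7, 7, 2, 1))
  on.exit({ par(op); grDevices::dev.off() }, add = TRUE)
  image(seq_len(k), seq_len(k), t(M[k:1, , drop = FALSE]),
        zlim = c(0, max(mx, .Machine$double.eps)), col = pal,
        axes = FALSE, xlab = "", ylab = "")
  axis(1, at = seq_len(k), labels = colnames(M), las = 2, cex.axis = 0.8)
  axis(2, at = seq_len(k), labels = rev(rownames(M)), las = 2, cex.axis = 0.8)
  title(main = sprintf("connection strength (%s)", cmatrix$mode))
  box()
  invisible(c(path, csv_path, json_path))
}
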