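# Molecular grid map: project fragment-embedding space onto a regular 2D
# cell lattice (PCA to 10 components, t-SNE to the plane, then an optimal
# linear assignment of points to cells) and overlay per-fragment properties.

#' Two-step 2D embedding of fragment vectors
#'
#' PCA to the top `min(10, k)` principal components followed by exact t-SNE
#' (perplexity 10, 3000 iterations by default) to two dimensions. The t-SNE
#' initial layout is drawn from a seeded generator, and the optimisation is
#' deterministic, so a fixed seed reproduces the coordinates. For small
#' inputs (`3 <= n < 31`) the perplexity is reduced to `(n - 1) / 3` with a
#' warning; fewer than 3 points is an error.
#'
#' @param vectors numeric matrix, one row per fragment (n x k).
#' @param seed integer seed for the t-SNE initialisation.
#' @param perplexity t-SNE perplexity (default 10).
#' @param max_iter gradient-descent iterations (default 3000).
#' @param n_components number of principal components retained before t-SNE
#'   (default 10, capped at k).
#' @return n x 2 coordinate matrix.
#' @export
embed_2d <- function(vectors, seed = 1L, perplexity = 10, max_iter = 3000L,
                     n_components = 10L) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n < 3L) stop("need at least 3 points for a 2D embedding", call. = FALSE)
  max_perp <- (n - 1) / 3
  if (perplexity > max_perp) {
    warning("perplexity reduced to ", signif(max_perp, 3), " for n = ", n)
    perplexity <- max_perp
  }
  k <- min(n_components, ncol(vectors), n - 1L)
  pcs <- stats::prcomp(vectors, center = TRUE, scale. = FALSE, rank. = k)$x
  set.seed(seed)
  y0 <- matrix(stats::rnorm(n * 2L, sd = 1e-4), n, 2L)
  tsne_exact(pcs, y0, perplexity, as.integer(max_iter))
}

#' Grid dimensions for a point count
#'
#' Near-square sizing rule: `cols = floor(sqrt(n))`,
#' `rows = ceiling(n / cols)`, so `rows >= cols` and the number of surplus
#' (dummy) cells `rows * cols - n` is the minimum achievable with that
#' column count. For the 26,795-fragment vocabulary this yields a
#' 165 x 163 lattice with 100 dummy cells.
#'
#' @param n_points number of fragments to place (>= 1).
#' @return named list `rows`, `cols`, `n_dummy`.
#' @examples
#' grid_dimensions(26795)
#' @export
grid_dimensions <- function(n_points) {
  stopifnot(n_points >= 1)
  n_points <- as.integer(n_points)
  cols <- max(1L, as.integer(floor(sqrt(n_points))))
  rows <- as.integer(ceiling(n_points / cols))
  list(rows = rows, cols = cols, n_dummy = rows * cols - n_points)
}

#' Assign 2D points to grid cells by optimal linear assignment
#'
#' Min-max normalises the point cloud onto the grid's lattice of cell
#' centres (so that a perfect rectangular arrangement of points reaches zero
#' cost) and solves the rectangular linear assignment of the n points to the
#' `rows * cols >= n` cell centres (at `(row - 0.5, col - 0.5)` in
#' normalised units) minimising total squared Euclidean distance, via a
#' Jonker-Volgenant-style shortest-augmenting-path solver. Cells left
#' without a point are dummy cells.
#'
#' @param coords n x 2 coordinate matrix (e.g. from [embed_2d()]).
#' @param rows,cols grid dimensions with `rows * cols >= n`.
#' @return object of class `grid_map`: `rows`, `cols`, `assignment`
#'   (data.frame `row`, `col` per point), `dummy_cells` (data.frame of
#'   unoccupied cells), and an empty `layers` list.
#' @export
assign_to_grid <- function(coords, rows, cols) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (rows * cols < n)
    stop("grid too small: ", rows, " x ", cols, " < ", n, " points",
         call. = FALSE)
  # map the point cloud onto the lattice of cell centres, so a perfect grid
  # of points can reach zero assignment cost
  norm01 <- function(v, hi) {
    rng <- range(v)
    if (diff(rng) == 0 || hi == 1) rep(hi / 2, length(v))
    else 0.5 + (v - rng[1L]) / diff(rng) * (hi - 1)
  }
  x <- norm01(coords[, 1L], rows)
  y <- norm01(coords[, 2L], cols)
  cell_row <- rep(seq_len(rows), each = cols)
  cell_col <- rep(seq_len(cols), times = rows)
  cx <- cell_row - 0.5
  cy <- cell_col - 0.5
  cost <- outer(x, cx, "-")^2 + outer(y, cy, "-")^2
  sel <- lap_solve(cost)
  assignment <- data.frame(row = cell_row[sel], col = cell_col[sel])
  occupied <- logical(rows * cols)
  occupied[sel] <- TRUE
  dummy <- data.frame(row = cell_row[!occupied], col = cell_col[!occupied])
  structure(list(rows = rows, cols = cols, assignment = assignment,
                 dummy_cells = dummy, layers = list(),
                 total_cost = sum(cost[cbind(seq_len(n), sel)])),
            class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  cat("Molecular grid map: ", x$rows, " x ", x$cols, " cells, ",
      nrow(x$assignment), " fragments, ", nrow(x$dummy_cells),
      " dummy cells\n", sep = "")
  if (length(x$layers))
    cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Calculated property layers for fragments
#'
#' Six standard properties per fragment, computed on the hydrogen-capped
#' structure: molecular weight (g/mol), LogP and topological polar surface
#' area (both from OpenBabel's contribution models), heavy-atom count,
#' aromatic-ring count and the fraction of sp3 carbon atoms (Fsp3).
#' Fragments that fail to parse are returned as `NA` rows with a warning.
#'
#' @param fragments character vector of fragment SMILES.
#' @return data.frame with columns `fragment_smiles`, `MW`, `LogP`, `TPSA`,
#'   `heavy_atoms`, `aromatic_rings`, `Fsp3`.
#' @export
property_layers <- function(fragments) {
  stopifnot(is.character(fragments))
  out <- data.frame(fragment_smiles = fragments,
                    MW = NA_real_, LogP = NA_real_, TPSA = NA_real_,
                    heavy_atoms = NA_integer_, aromatic_rings = NA_integer_,
                    Fsp3 = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(fragments)) {
    g <- tryCatch(hcap_graph(smiles_to_graph(fragments[i])),
                  error = function(e) NULL)
    if (is.null(g) || n_atoms(g) == 0L) {
      warning("skipping unparsable fragment: ", fragments[i])
      next
    }
    capped <- graph_to_smiles(g)
    pr <- tryCatch(
      ChemmineOB::forEachMol("SMILES", capped, ChemmineOB::prop_OB)[[1L]],
      error = function(e) NULL)
    if (!is.null(pr)) {
      out$MW[i] <- pr$MW[1L]
      out$LogP[i] <- pr$logP[1L]
      out$TPSA[i] <- pr$TPSA[1L]
    }
    ai <- aromatic_info(g)
    out$heavy_atoms[i] <- n_heavy(g)
    out$aromatic_rings[i] <- sum(ai$aromatic)
    carbons <- which(g$symbol == "C")
    if (length(carbons)) {
      has_multiple <- logical(n_atoms(g))
      if (nrow(g$bond)) for (b in seq_len(nrow(g$bond))) {
        if (g$bond[b, 3L] >= 2L) {
          has_multiple[g$bond[b, 1L]] <- TRUE
          has_multiple[g$bond[b, 2L]] <- TRUE
        }
      }
      sp3 <- !has_multiple[carbons] & !ai$atom[carbons]
      out$Fsp3[i] <- mean(sp3)
    } else {
      out$Fsp3[i] <- 0
    }
  }
  out
}

#' Build a property-annotated molecular grid map
#'
#' Convenience wrapper: embeds the model's EFVs (or a supplied vector
#' matrix) in 2D, sizes the grid with [grid_dimensions()], assigns fragments
#' to cells, and attaches the six [property_layers()].
#'
#' @param model an `efv_model`, or a numeric matrix with fragment rownames.
#' @param seed seed for the 2D embedding.
#' @param perplexity,max_iter t-SNE settings, see [embed_2d()].
#' @return a `grid_map` whose `assignment` carries `fragment_smiles` and
#'   whose `layers` hold the property columns.
#' @export
build_grid_map <- function(model, seed = 1L, perplexity = 10,
                           max_iter = 3000L) {
  vecs <- if (inherits(model, "efv_model")) model$vectors else as.matrix(model)
  frags <- rownames(vecs)
  if (is.null(frags)) stop("vectors must have fragment rownames", call. = FALSE)
  coords <- embed_2d(vecs, seed = seed, perplexity = perplexity,
                     max_iter = max_iter)
  dims <- grid_dimensions(nrow(vecs))
  gm <- assign_to_grid(coords, dims$rows, dims$cols)
  gm$assignment$fragment_smiles <- frags
  props <- property_layers(frags)
  gm$layers <- props[, c("MW", "LogP", "TPSA", "heavy_atoms",
                         "aromatic_rings", "Fsp3")]
  gm
}

#' Write a grid map as TSV
#'
#' One row per fragment: `fragment_smiles`, `row`, `col` and any property
#' layers; dummy cells are omitted (they carry no fragment).
#'
#' @param gm a `grid_map` from [build_grid_map()].
#' @param path file path.
#' @export
write_grid_map <- function(gm, path) {
  df <- gm$assignment
  if (length(gm$layers)) df <- cbind(df, gm$layers)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Heatmap rendering of one grid-map layer
#'
#' @param x a `grid_map` with property layers.
#' @param layer layer name (default `"MW"`).
#' @param ... passed to [graphics::image()].
#' @export
plot.grid_map <- function(x, layer = "MW", ...) {
  if (!layer %in% names(x$layers))
    stop("no such layer: ", layer, call. = FALSE)
  z <- matrix(NA_real_, x$rows, x$cols)
  z[cbind(x$assignment$row, x$assignment$col)] <- x$layers[[layer]]
  graphics::image(seq_len(x$cols), seq_len(x$rows), t(z),
                  xlab = "column", ylab = "row", main = layer,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
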