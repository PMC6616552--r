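# Alpha diversity, rarefied richness, Bray-Curtis, PCoA -----------------------

#' Shannon diversity (natural log)
#'
#' H = -sum p_i ln p_i over the sample's taxon proportions, computed through
#' vegan. Natural-log units (nats); invariant under rescaling of counts.
#'
#' @param counts nonnegative count (or proportion) vector for one sample.
#' @return Shannon index in nats.
#' @export
shannon_diversity <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  if (sum(counts) == 0) stop("zero-sum sample")
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Expected (rarefied) richness at fixed depth
#'
#' E[S_n] = sum_i [1 - C(N - N_i, n) / C(N, n)]: the expected number of taxa
#' in a without-replacement subsample of n reads, evaluated through vegan
#' (which works in log-space for stability).
#'
#' @param counts integer count vector for one sample.
#' @param depth subsample depth n; must not exceed the sample's total reads.
#' @return expected number of taxa (real).
#' @export
rarefied_richness <- function(counts, depth) {
  N <- sum(counts)
  if (depth > N) stop("rarefaction depth ", depth, " exceeds total reads ", N)
  # vegan warns heuristically about singleton-dominated rows; depth validity
  # is already checked above
  unname(c(suppressWarnings(
    vegan::rarefy(matrix(counts, nrow = 1), sample = depth))))
}

#' Per-sample diversity records
#'
#' @param x an [otu_table()].
#' @param depth rarefaction depth; defaults to the minimum library size of
#'   the table's samples (recorded in the output).
#' @return data.frame (sample_id, shannon, richness_observed,
#'   richness_rarefied, rarefaction_depth).
#' @export
diversity_table <- function(x, depth = NULL) {
  m <- x$counts
  if (is.null(depth)) depth <- min(colSums(m))
  data.frame(
    sample_id = colnames(m),
    shannon = apply(m, 2, shannon_diversity),
    richness_observed = colSums(m > 0),
    richness_rarefied = apply(m, 2, rarefied_richness, depth = depth),
    rarefaction_depth = depth,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between two samples
#'
#' Weighted: sum |a_i - b_i| / sum (a_i + b_i). Unweighted: computed on the
#' presence pattern (count > 0), equal to (A + B - 2J)/(A + B) with A, B the
#' two richness values and J the shared taxa.
#'
#' @param a,b nonnegative vectors on the same taxon axis (relative abundances
#'   for the weighted flavor).
#' @param flavor `"weighted"` or `"unweighted"`.
#' @return dissimilarity in [0, 1].
#' @export
bray_curtis <- function(a, b, flavor = c("weighted", "unweighted")) {
  flavor <- match.arg(flavor)
  if (length(a) != length(b)) stop("vectors on different taxon axes")
  if (sum(a) == 0 && sum(b) == 0) stop("both vectors all-zero")
  m <- rbind(a, b)
  as.numeric(vegan::vegdist(m, method = "bray",
                            binary = (flavor == "unweighted")))
}

#' Pairwise Bray-Curtis distance matrix
#'
#' All-vs-all distances across a table's samples via `vegan::vegdist`
#' (samples are transposed to rows for vegan). The weighted flavor should be
#' fed relative abundances; unweighted uses presence/absence of the filtered
#' counts.
#'
#' @param x an [otu_table()] or [to_relative_abundance()] result.
#' @param flavor `"weighted"` or `"unweighted"`.
#' @return object of class `dist_matrix`: list with `d` (symmetric matrix,
#'   zero diagonal), `flavor`, `sample_ids`.
#' @export
distance_matrix <- function(x, flavor = c("weighted", "unweighted")) {
  flavor <- match.arg(flavor)
  m <- if (inherits(x, "rel_abundance")) x$values else x$counts
  d <- as.matrix(vegan::vegdist(t(m), method = "bray",
                                binary = (flavor == "unweighted")))
  structure(list(d = d, flavor = flavor, sample_ids = colnames(m)),
            class = "dist_matrix")
}

#' Serialize / read a distance matrix as labeled square TSV
#'
#' @param dm a `dist_matrix` (or square labeled matrix).
#' @param path file path.
#' @export
write_distance_matrix <- function(dm, path) {
  d <- if (inherits(dm, "dist_matrix")) dm$d else dm
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @param flavor flavor tag to attach on read.
#' @export
read_distance_matrix <- function(path, flavor = "weighted") {
  df <- read_tsv_raw(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  structure(list(d = m, flavor = flavor, sample_ids = rownames(m)),
            class = "dist_matrix")
}

as_dist_input <- function(dm) {
  if (inherits(dm, "dist_matrix")) dm$d
  else if (inherits(dm, "dist")) as.matrix(dm)
  else as.matrix(dm)
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers -D^2/2 and eigendecomposes. Coordinates are returned for
#' positive eigenvalues only; all eigenvalues (including negative ones, which
#' arise for non-Euclidean dissimilarities such as Bray-Curtis) are reported.
#' Axis orientation is fixed by flipping each axis so its largest-magnitude
#' loading is positive.
#'
#' @param dm a `dist_matrix`, `dist`, or square symmetric matrix.
#' @return list with `coordinates` (samples x positive axes), `eigenvalues`
#'   (all, descending), `prop_explained` (over positive eigenvalues).
#' @export
pcoa <- function(dm) {
  d <- as_dist_input(dm)
  if (nrow(d) < 3) stop("PCoA needs at least 3 samples")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  n <- nrow(d)
  cs <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- cs$eig
  pos <- which(eig > max(eig, 0) * 1e-10 & eig > 0)
  if (length(pos) == 0) {
    coords <- matrix(0, nrow = n, ncol = 0, dimnames = list(rownames(d), NULL))
    return(list(coordinates = coords, eigenvalues = eig,
                prop_explained = numeric(0)))
  }
  coords <- cs$points[, pos, drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig,
       prop_explained = eig[pos] / sum(eig[pos]))
}
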