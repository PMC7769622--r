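#' Construct a ScanPath
#'
#' @param locations numeric T x 2 matrix (or data.frame) of (x, y) pixel
#'   coordinates, T >= 2.
#' @param tags optional character vector of per-fixation generation tags
#'   ("initial" for the first two fixations, then "local"/"global").
#' @return a [ScanPath-class].
#' @export
scanPath <- function(locations, tags = character(0)) {
  locations <- as.matrix(locations)
  storage.mode(locations) <- "double"
  colnames(locations) <- c("x", "y")
  new("ScanPath", locations = unname(locations), tags = as.character(tags))
}

#' @rdname lgattention-generics
#' @export
setMethod("locations", "ScanPath", function(x) {
  out <- x@locations
  colnames(out) <- c("x", "y")
  out
})

#' @rdname lgattention-generics
#' @export
setMethod("pathTags", "ScanPath", function(x) x@tags)

#' @rdname lgattention-generics
#' @export
setMethod("nFixations", "ScanPath", function(x) nrow(x@locations))

setMethod("length", "ScanPath", function(x) nrow(x@locations))

setMethod("show", "ScanPath", function(object) {
  n <- nrow(object@locations)
  cat(sprintf("ScanPath: %d fixations", n))
  if (length(object@tags))
    cat(sprintf(" (%d local, %d global)",
                sum(object@tags == "local"), sum(object@tags == "global")))
  cat("\n")
})

.FIX_COLS <- c("subject_id", "image_id", "trial_id", "fixation_index", "x", "y")

#' Validate a fixation table
#'
#' Checks the six canonical columns, grid bounds (0 <= x < W, 0 <= y < H) and
#' that `fixation_index` increases strictly from 1 within each trial. Returns
#' the table with columns in canonical order.
#'
#' @param fixations data.frame with columns `subject_id`, `image_id`,
#'   `trial_id`, `fixation_index`, `x`, `y`.
#' @param grid integer (H, W) pixel counts, or NULL to skip bound checks.
#' @return the validated data.frame (canonical column order).
#' @export
validateFixationTable <- function(fixations, grid = NULL) {
  missing <- setdiff(.FIX_COLS, names(fixations))
  if (length(missing))
    stop("fixation table is missing column(s): ", paste(missing, collapse = ", "))
  fixations <- as.data.frame(fixations)[, .FIX_COLS]
  if (!is.null(grid)) {
    H <- grid[1]; W <- grid[2]
    bad <- which(fixations$x < 0 | fixations$x >= W |
                 fixations$y < 0 | fixations$y >= H | !complete.cases(fixations))
    if (length(bad))
      stop("fixation rows outside the ", H, " x ", W, " grid: rows ",
           paste(head(bad, 10L), collapse = ", "),
           if (length(bad) > 10L) " ..." else "")
  }
  key <- interaction(fixations$subject_id, fixations$image_id,
                     fixations$trial_id, drop = TRUE)
  for (tr in split(fixations$fixation_index, key)) {
    if (tr[1] != 1L || any(diff(tr) <= 0))
      stop("'fixation_index' must increase strictly from 1 within each trial")
  }
  fixations
}

#' Load / write a fixation table (CSV or TSV)
#'
#' The on-disk format is a delimited text file with a header row naming the
#' six canonical columns (any column order); the delimiter is inferred from
#' the extension/content (comma or tab).
#'
#' @param path file path.
#' @param grid integer (H, W) pixel counts used to reject out-of-bounds rows
#'   (NULL skips the check).
#' @param fixations a fixation table (for writing).
#' @return `loadFixationTable` returns the validated data.frame.
#' @export
loadFixationTable <- function(path, grid = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  validateFixationTable(tab, grid)
}

#' @rdname loadFixationTable
#' @export
writeFixationTable <- function(fixations, path) {
  fixations <- validateFixationTable(fixations)
  write.csv(fixations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Split a fixation table into ScanPath objects, one per trial, keyed by
# "subject|image|trial"; image ids are carried in the "image_id" attribute.
fixationsToPaths <- function(fixations) {
  fixations <- validateFixationTable(fixations)
  key <- interaction(fixations$subject_id, fixations$image_id,
                     fixations$trial_id, drop = TRUE, sep = "|")
  split_rows <- split(seq_len(nrow(fixations)), key)
  paths <- lapply(split_rows, function(ix) {
    rows <- fixations[ix, ][order(fixations$fixation_index[ix]), ]
    p <- scanPath(cbind(rows$x, rows$y))
    attr(p, "subject_id") <- rows$subject_id[1]
    attr(p, "image_id") <- rows$image_id[1]
    attr(p, "trial_id") <- rows$trial_id[1]
    p
  })
  paths
}

#' Synthetic scene-viewing dataset with ground truth
#'
#' Generates a dataset emulating a scene-viewing experiment: for each
#' (subject, image) pair one scan path of `nFix` fixations is simulated from
#' the model on a per-image synthetic saliency map. With `nImages = 30` and
#' `nFix` around 35 (roughly 10 s of viewing at 3.5 saccades per second) the
#' dataset size per subject matches a typical single-subject experiment.
#'
#' @param params a [ModelParams-class]: the ground-truth parameters.
#' @param nSubjects,nImages number of subjects and images.
#' @param nFix fixations per scan path (>= 3).
#' @param grid integer (H, W) pixel counts of the synthetic maps.
#' @param pxPerDegree pixel scale stored on the maps.
#' @param nModes Gaussian bumps per synthetic map.
#' @param seed integer master seed; the maps and every path get reproducible
#'   sub-seeds.
#' @return list with elements `fixations` (fixation table), `maps` (named
#'   list of [SaliencyMap-class], one per image), and `truth` (list with the
#'   generating parameter vector, the seed, and the per-fixation latent tags).
#' @export
syntheticDataset <- function(params, nSubjects = 1L, nImages = 30L,
                             nFix = 35L, grid = c(128L, 128L),
                             pxPerDegree = grid[2] / 32,
                             nModes = 3L, seed = NULL) {
  stopifnot(is(params, "ModelParams"))
  if (nFix < 3L) stop("'nFix' must be >= 3")
  seeds <- spawn_seeds(seed, nImages + nSubjects * nImages)
  image_ids <- sprintf("img%02d", seq_len(nImages))
  maps <- setNames(lapply(seq_len(nImages), function(i)
    syntheticSaliency(grid, nModes = nModes, seed = seeds[[i]],
                      pxPerDegree = pxPerDegree)), image_ids)
  rows <- vector("list", nSubjects * nImages)
  tag_rows <- vector("list", nSubjects * nImages)
  k <- 0L
  for (s in seq_len(nSubjects)) {
    for (i in seq_len(nImages)) {
      k <- k + 1L
      path <- sampleScanpath(maps[[i]], params, nFix = nFix,
                             seed = seeds[[nImages + k]], recordTags = TRUE)
      loc <- locations(path)
      rows[[k]] <- data.frame(
        subject_id = sprintf("subj%02d", s), image_id = image_ids[i],
        trial_id = 1L, fixation_index = seq_len(nFix),
        x = loc[, "x"], y = loc[, "y"])
      tg <- pathTags(path)
      if (length(tg))
        tag_rows[[k]] <- data.frame(
          subject_id = sprintf("subj%02d", s), image_id = image_ids[i],
          trial_id = 1L, fixation_index = seq_len(nFix), tag = tg)
    }
  }
  list(fixations = do.call(rbind, rows),
       maps = maps,
       truth = list(params = coef(params), variant = variantName(params),
                    seed = if (is.null(seed)) NA_integer_ else seed,
                    tags = if (length(tag_rows) && !is.null(tag_rows[[1]]))
                             do.call(rbind, tag_rows) else NULL))
}
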