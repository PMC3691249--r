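## Readers and writers for the pipeline's on-disk formats: expression
## matrices as (gzipped) tab-delimited or MatrixMarket with side-car id
## lists, annotation tables as TSV, configs as YAML.

#' Write / read an expression matrix
#'
#' Tab-delimited layout: features in rows, first column `feature_id`, header
#' row of sample ids; values are written with full precision so read/write
#' round-trips are exact to 1e-12. MatrixMarket (`mtx`) layout writes the
#' matrix plus `<path>.rownames` / `<path>.colnames` side-car id lists.
#' Paths ending in `.gz` are compressed (tsv only).
#'
#' @param x numeric matrix with feature ids as rownames and sample ids as
#'   colnames.
#' @param path output file.
#' @param format `"tsv"` or `"mtx"`.
#' @return `writeExprMatrix()`: the path, invisibly. `readExprMatrix()`: the
#'   matrix with dimnames restored.
#' @export
writeExprMatrix <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("feature_id", colnames(x)), collapse = "\t"), con)
    body <- apply(format(x, digits = 17, scientific = TRUE, trim = TRUE), 1L,
                  paste, collapse = "\t")
    writeLines(paste(rownames(x), body, sep = "\t"), con)
  } else {
    Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE), path)
    writeLines(rownames(x), paste0(path, ".rownames"))
    writeLines(colnames(x), paste0(path, ".colnames"))
  }
  invisible(path)
}

#' @rdname writeExprMatrix
#' @export
readExprMatrix <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            colClasses = "character")
    if (colnames(df)[1L] != "feature_id")
      stop("malformed header: first column must be 'feature_id', found '",
           colnames(df)[1L], "'")
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    if (anyNA(m)) stop("non-numeric values in the expression matrix body")
    rownames(m) <- df$feature_id
    m
  } else {
    m <- as.matrix(Matrix::readMM(path))
    rn <- paste0(path, ".rownames"); cn <- paste0(path, ".colnames")
    if (!file.exists(rn) || !file.exists(cn))
      stop("missing side-car id lists: ", rn, " / ", cn)
    rownames(m) <- readLines(rn)
    colnames(m) <- readLines(cn)
    m
  }
}

#' Write / read an annotation table
#'
#' Plain tab-delimited tables with a header row; row names are carried in
#' the first column.
#'
#' @param df data.frame.
#' @param path file path.
#' @return `readAnnotation()`: the data.frame.
#' @export
writeAnnotation <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnnotation
#' @export
readAnnotation <- function(path) {
  utils::read.delim(path, header = TRUE, check.names = FALSE)
}

#' Write / read a pipeline configuration as YAML
#'
#' Serializes the simulation, selection and forest configurations (plain
#' lists of scalars) to a YAML file and restores them.
#'
#' @param config a named list (e.g. from [pipelineConfig()]).
#' @param path file path.
#' @return `readPipelineConfig()`: the restored configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  drop_class <- function(x) {
    if (is.list(x)) return(lapply(unclass(x), drop_class))
    if (isS4(x)) {
      out <- lapply(slotNames(class(x)), function(s) slot(x, s))
      names(out) <- slotNames(class(x))
      return(out)
    }
    x
  }
  yaml::write_yaml(drop_class(config), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list(master_seed = raw$master_seed %||% 1L,
              output_dir = raw$output_dir)
  if (!is.null(raw$simulation))
    out$simulation <- do.call(simConfig, raw$simulation)
  if (!is.null(raw$input)) out$input <- raw$input
  out$selection <- do.call(selectionConfig, raw$selection %||% list())
  out$forest <- do.call(forestConfig, raw$forest %||% list())
  out$evaluation <- raw$evaluation %||% list()
  if (!is.null(out$simulation) && !is.null(out$input))
    stop("supply exactly one of a simulation config or input paths")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
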