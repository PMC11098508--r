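#' Read and write site tables
#'
#' The sites CSV dialect has a header row and columns `lon,lat,t` — `lon`
#' and `lat` are the site coordinates (planar x/y or degrees, depending on
#' the distance mode used downstream) and `t` is an optional 0-based integer
#' resource type.
#'
#' @param path CSV file path.
#' @return `read_sites`: data frame with columns `x`, `y`, `t`.
#' @export
read_sites <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("lon", "lat") %in% names(df)))
    stop("sites CSV needs 'lon' and 'lat' columns")
  out <- data.frame(x = as.numeric(df$lon), y = as.numeric(df$lat))
  out$t <- if (!is.null(df$t)) as.integer(df$t) else 0L
  out
}

#' @rdname read_sites
#' @param sites site data frame (columns `x`, `y`, optional `t`).
#' @export
write_sites <- function(sites, path) {
  df <- data.frame(lon = sites$x, lat = sites$y, t = site_types(sites))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write masking matrices
#'
#' Square numeric CSV whose header row carries the resource-type labels;
#' rows index the source type, columns the destination type.
#'
#' @param path CSV file path.
#' @export
read_mask <- function(path) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  if (nrow(m) != ncol(m)) stop("mask CSV must be square")
  storage.mode(m) <- "double"
  m
}

#' @rdname read_mask
#' @param mask square mask matrix.
#' @export
write_mask <- function(mask, path) {
  mask <- as.matrix(mask)
  if (is.null(colnames(mask))) colnames(mask) <- seq_len(ncol(mask)) - 1L
  utils::write.csv(mask, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write movement matrices
#'
#' Plain headerless CSV of the row-stochastic movement matrix, suitable for
#' consumption by downstream spatial population simulators.
#'
#' @param path CSV file path.
#' @export
read_movement_matrix <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

#' @rdname read_movement_matrix
#' @param tau movement matrix.
#' @export
write_movement_matrix <- function(tau, path) {
  utils::write.table(tau, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read and write trap tables
#'
#' Columns: `id,placement_kind,node_or_x,y,kernel,A,radius,shape,immovable`
#' with `placement_kind` either `node` (discrete, `node_or_x` a 0-based site
#' index, `y` empty) or `coord` (continuous, `node_or_x`/`y` coordinates);
#' `kernel` one of the built-in trap kernel families; `shape` empty unless
#' sigmoidal; `immovable` 0/1.
#'
#' @param path CSV file path.
#' @return `read_traps`: list of [trap()] objects.
#' @export
read_traps <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "placement_kind", "node_or_x", "y", "kernel", "A",
            "radius", "shape", "immovable")
  if (!all(need %in% names(df))) stop("traps CSV is missing required columns")
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    kern <- trap_kernel(as.character(r$kernel), A = r$A, radius = r$radius,
                        shape = if (is.na(r$shape)) NULL else r$shape)
    if (r$placement_kind == "node")
      trap(kern, node = as.integer(r$node_or_x), immovable = r$immovable == 1)
    else
      trap(kern, x = as.numeric(r$node_or_x), y = as.numeric(r$y),
           immovable = r$immovable == 1)
  })
}

#' @rdname read_traps
#' @param traps list of [trap()] objects.
#' @export
write_traps <- function(traps, path) {
  rows <- lapply(seq_along(traps), function(i) {
    tr <- traps[[i]]
    data.frame(id = i - 1L,
               placement_kind = if (!is.null(tr$node)) "node" else "coord",
               node_or_x = if (!is.null(tr$node)) tr$node else tr$x,
               y = if (!is.null(tr$node)) NA else tr$y,
               kernel = tr$kernel$family, A = tr$kernel$A,
               radius = tr$kernel$radius,
               shape = if (is.null(tr$kernel$shape)) NA else tr$kernel$shape,
               immovable = as.integer(tr$immovable))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export an optimization result
#'
#' `write_opt_result` writes a JSON report (best placement, fitness,
#' objective, mode, seed and the full per-generation trace);
#' `write_opt_trace` writes one `generation,best_fitness,mean_fitness` CSV
#' per repetition, suffixed `_rep<k>`.
#'
#' @param fit a `trap_opt`.
#' @param path output JSON path.
#' @export
write_opt_result <- function(fit, path) {
  placement <- if (fit$mode == "discrete") as.integer(fit$best_genes) else {
    m <- fit$best_genes
    lapply(seq_len(nrow(m)), function(i) c(x = m[i, 1], y = m[i, 2]))
  }
  obj <- list(best_placement = placement,
              best_fitness_days = fit$best_fitness,
              objective = fit$objective, mode = fit$mode, seed = fit$seed,
              trace = lapply(seq_len(nrow(fit$trace)), function(i)
                list(rep = fit$trace$repetition[i],
                     gen = fit$trace$generation[i],
                     best = fit$trace$best[i],
                     mean = fit$trace$mean[i])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_opt_result
#' @param stem output path stem for trace CSVs.
#' @export
write_opt_trace <- function(fit, stem) {
  paths <- character(0)
  for (r in unique(fit$trace$repetition)) {
    sub <- fit$trace[fit$trace$repetition == r, ]
    p <- sprintf("%s_rep%d.csv", stem, r)
    utils::write.csv(data.frame(generation = sub$generation,
                                best_fitness = sub$best,
                                mean_fitness = sub$mean),
                     p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values are parsed
#' as numbers where possible, otherwise kept as strings. Command-line flags
#' of the bundled CLI override file values.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop(sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
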