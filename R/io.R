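#' Read / write long-format event-history CSV
#'
#' The long format has one row per sojourn: columns `id`, `from`, `to`,
#' `entry`, `exit`, `status` (1 = event, 0 = censored); `to` is blank for
#' censored rows.  Numbers are written with 17 significant digits so a
#' write/read round trip is lossless.
#'
#' @param path file path.
#' @param space optional [msm_space] for validation (inferred otherwise).
#' @param data an `msm_events` data.frame.
#' @return `read_events()` returns a validated `msm_events` data.frame;
#'   `write_events()` returns `path` invisibly.
#' @export
read_events <- function(path, space = NULL) {
  df <- utils::read.csv(path, colClasses = c(to = "character"))
  need <- c("id", "from", "to", "entry", "exit", "status")
  if (!all(need %in% names(df))) {
    stop("events CSV needs header ", paste(need, collapse = ","))
  }
  df$to[df$to == ""] <- NA
  df$to <- as.integer(df$to)
  df$from <- as.integer(df$from)
  df$status <- as.integer(df$status)
  bad <- which(!(df$entry < df$exit))
  if (length(bad)) {
    stop("entry >= exit in row ", paste(bad, collapse = ", "), " of ", path)
  }
  bad <- which(df$status == 0L & !is.na(df$to))
  if (length(bad)) {
    stop("censored records must not name a destination (row ",
         paste(bad, collapse = ", "), ")")
  }
  if (is.null(space)) space <- infer_space(df)
  validate_event_history(df, space)
  o <- order(df$id, df$entry)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  st0 <- df$from[!duplicated(df$id)]
  structure(df,
            subjects = data.frame(id = unique(df$id), state0 = st0),
            space = space,
            class = c("msm_events", "data.frame"))
}

fmt17 <- function(x) {
  ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))
}

#' @rdname read_events
#' @export
write_events <- function(data, path) {
  out <- data.frame(id = data$id, from = data$from,
                    to = ifelse(is.na(data$to), "", as.character(data$to)),
                    entry = fmt17(data$entry), exit = fmt17(data$exit),
                    status = data$status)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write hazard-increment CSV
#'
#' Columns `time`, `from`, `to`, `increment` (optionally `risk_set`), one row
#' per transition with positive increment.  A cumulative-hazard variant with
#' column `cumhaz` instead of `increment` -- the natural format when
#' digitizing published Nelson-Aalen plots -- is differenced per transition
#' (the cumulative must be nondecreasing).
#'
#' @param path file path.
#' @param space optional [msm_space]; inferred otherwise (labels never seen
#'   in `from` are taken as absorbing).
#' @param tab an [increment_table()].
#' @return `read_increments()` returns an `msm_increments` table;
#'   `write_increments()` returns `path` invisibly.
#' @export
read_increments <- function(path, space = NULL) {
  df <- utils::read.csv(path)
  if ("cumhaz" %in% names(df) && !"increment" %in% names(df)) {
    df <- df[order(df$from, df$to, df$time), , drop = FALSE]
    parts <- split(df, paste(df$from, df$to))
    df <- do.call(rbind, lapply(parts, function(p) {
      inc <- diff(c(0, p$cumhaz))
      if (any(inc < -1e-12)) {
        stop("cumulative hazard for ", p$from[1], "->", p$to[1],
             " is not nondecreasing")
      }
      p$increment <- pmax(inc, 0)
      p$cumhaz <- NULL
      p[p$increment > 0, , drop = FALSE]
    }))
  }
  need <- c("time", "from", "to", "increment")
  if (!all(need %in% names(df))) {
    stop("increments CSV needs header time,from,to,increment (or cumhaz)")
  }
  increment_table(df, space)
}

#' @rdname read_increments
#' @export
write_increments <- function(tab, path) {
  out <- data.frame(time = fmt17(tab$time), from = tab$from, to = tab$to,
                    increment = fmt17(tab$increment))
  if (!is.null(tab$risk_set)) out$risk_set <- tab$risk_set
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a JSON model configuration
#'
#' Serializes the configuration-list format of [as_msm_model()] /
#' [preset()].
#'
#' @param path file path.
#' @param config configuration list.
#' @return `read_model_config()` returns the configuration list;
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg$states <- as.integer(unlist(cfg$states))
  if (!is.null(cfg$absorbing)) cfg$absorbing <- as.integer(unlist(cfg$absorbing))
  cfg
}

#' @rdname read_model_config
#' @export
write_model_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# One manifest per CLI run: command, config echo, seed, version, timestamp,
# md5 digests of the outputs.  Reruns with the same inputs and seed yield
# byte-identical outputs (the timestamp is the only varying field).
write_manifest <- function(command, args, outputs, seed = NULL) {
  manifest <- list(
    command = command,
    args = as.list(args),
    seed = seed,
    package = "emsim",
    version = as.character(utils::packageVersion("emsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(outputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
  )
  path <- paste0(outputs[[1L]], ".manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
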