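#' Write a trajectory to CSV
#'
#' CSV with header `tick,S,E,I,R`; compartments absent from the model are
#' written as empty fields. Numbers are formatted to 6 significant digits.
#'
#' @param traj A `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)[, c("tick", "S", "E", "I", "R")]
  fmt <- function(x) ifelse(is.na(x), "",
                            trimws(formatC(signif(x, 6), format = "fg",
                                           digits = 6)))
  lines <- c("tick,S,E,I,R",
             do.call(paste, c(list(df$tick), lapply(df[-1], fmt), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trajectory from CSV
#'
#' Inverse of [write_trajectory()] up to formatting precision. The model
#' class is inferred from the populated compartments (`S,I` gives SI,
#' `S,I,R` SIR, `S,E,I,R` SEIRS) unless given explicitly. Malformed rows
#' raise a parse error naming the offending line.
#'
#' @param path CSV file with header `tick,S,E,I,R`.
#' @param model Optional model-name override for the inferred spec.
#' @return A `trajectory` (kind `"file"`).
#' @export
read_trajectory <- function(path, model = NULL) {
  if (!file.exists(path))
    stop("trajectory file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 1 || trimws(lines[1]) != "tick,S,E,I,R")
    stop("parse error at line 1: expected header 'tick,S,E,I,R'",
         call. = FALSE)
  n <- length(lines) - 1
  cols <- matrix(NA_real_, n, 5)
  for (i in seq_len(n)) {
    parts <- strsplit(lines[i + 1], ",", fixed = TRUE)[[1]]
    length(parts) <- 5
    for (j in 1:5) {
      v <- parts[j]
      if (is.na(v) || v == "") next
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num))
        stop("parse error at line ", i + 1, ": non-numeric value '", v, "'",
             call. = FALSE)
      cols[i, j] <- num
    }
    if (is.na(cols[i, 1]))
      stop("parse error at line ", i + 1, ": missing tick", call. = FALSE)
  }
  present <- c("S", "E", "I", "R")[colSums(!is.na(cols[, 2:5, drop = FALSE])) > 0]
  if (is.null(model)) {
    model <- if (setequal(present, c("S", "I"))) "SI"
             else if (setequal(present, c("S", "I", "R"))) "SIR"
             else "SEIRS"
  }
  as_trajectory(tick = cols[, 1], S = cols[, 2], E = cols[, 3], I = cols[, 4],
                R = cols[, 5], spec = make_model_spec(model),
                params = list(path = path), kind = "file")
}

#' Read or write an acceptance series CSV (`week,S_RW,I_RW`)
#' @param path CSV path.
#' @return [acceptance_series()] for the reader; `path` for the writer.
#' @export
read_acceptance_series <- function(path) {
  df <- utils::read.csv(path)
  need <- c("week", "S_RW", "I_RW")
  if (!all(need %in% names(df)))
    stop("expected columns week,S_RW,I_RW", call. = FALSE)
  acceptance_series(df$week, df$S_RW, df$I_RW)
}

#' @rdname read_acceptance_series
#' @param series An [acceptance_series()].
#' @export
write_acceptance_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write the long-format sweep metrics to CSV
#' @param sweep A `sweep_result`.
#' @param path Output path.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.csv(sweep$metrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a run configuration as YAML
#'
#' Round-trips [world_config()]/[enhanced_config()] objects (the `spec`
#' field is rebuilt from the model name on read).
#'
#' @param config A `world_config`.
#' @param path YAML file path.
#' @return The configuration (reader) or `path` (writer).
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$spec <- NULL
  x$type <- if (isTRUE(config$enhanced)) "enhanced" else "simple"
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  type <- x$type %||% "simple"
  x$type <- NULL; x$enhanced <- NULL
  common <- c("model", "M", "N", "beta", "sigma", "gamma", "xi", "case",
              "I0", "E0", "r", "theta", "d_c", "d_e", "e_c", "e0", "growth",
              "q_max", "seed", "contact_scale")
  if (type == "enhanced") {
    keep <- c(common, "group_fraction", "homophily", "I_R", "L_M_S", "L_M_I",
              "L_P_S", "L_P_I", "D_P_S", "D_P_I", "post_quantum",
              "consume_bite")
    do.call(enhanced_config, x[intersect(keep, names(x))])
  } else {
    do.call(world_config, x[intersect(common, names(x))])
  }
}

#' Write a run manifest
#'
#' JSON snapshot of a command, its full configuration, seeds, package
#' version and output paths; re-running a deterministic command from its
#' manifest reproduces its outputs bit-identically.
#'
#' @param path Manifest path (JSON).
#' @param command Command or function name.
#' @param config Configuration object or list.
#' @param seed Seed(s) used.
#' @param outputs Character vector of produced files.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config, seed, outputs) {
  if (inherits(config, "world_config")) {
    config <- unclass(config); config$spec <- NULL
  }
  jsonlite::write_json(
    list(command = command, config = config, seed = seed,
         package = "infodemsim",
         version = as.character(utils::packageVersion("infodemsim")),
         outputs = outputs),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
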