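## Loading, validation and pre-processing of relocation data.

#' Read relocation fixes from a delimited text file
#'
#' Reads a CSV (or other delimited) file of relocations into a
#' \code{\linkS4class{Trajectory}}.  Column names are configurable through
#' \code{columnMap}; timestamps may be ISO-8601 strings or epoch seconds.
#' Coordinates are assumed to be in a projected planar CRS (map units);
#' no reprojection is performed.
#'
#' @param path path to the input file.
#' @param columnMap named character vector mapping the roles \code{x},
#'   \code{y}, \code{t} (and optionally \code{id}) to column names in the
#'   file.
#' @param timeFormat "auto" (numeric column = epoch seconds, character
#'   column = ISO-8601), "epoch", or "iso8601".
#' @param tz time zone used for ISO-8601 parsing.
#' @param sep field separator.
#' @return A \code{\linkS4class{Trajectory}} sorted by time.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(x = c(0, 3, 6), y = c(0, 4, 8),
#'                      t = c(0, 10, 20)), f, row.names = FALSE)
#' readFixes(f)
#' @export
readFixes <- function(path, columnMap = c(x = "x", y = "y", t = "t"),
                      timeFormat = c("auto", "epoch", "iso8601"),
                      tz = "UTC", sep = ",") {
  timeFormat <- match.arg(timeFormat)
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("x", "y", "t")
  if (!all(need %in% names(columnMap)))
    stop("columnMap must name columns for x, y and t")
  missingCols <- setdiff(unname(columnMap[need]), names(df))
  if (length(missingCols))
    stop("mapped column(s) not present in file: ",
         paste(missingCols, collapse = ", "))
  for (nm in c("x", "y")) {
    v <- df[[columnMap[[nm]]]]
    bad <- which(is.na(suppressWarnings(as.numeric(v))))
    if (length(bad))
      stop("non-numeric ", nm, " coordinate at data row ", bad[1L])
  }
  xs <- as.numeric(df[[columnMap[["x"]]]])
  ys <- as.numeric(df[[columnMap[["y"]]]])
  tv <- df[[columnMap[["t"]]]]
  tsec <- .parseTimes(tv, timeFormat, tz)
  id <- if ("id" %in% names(columnMap) && columnMap[["id"]] %in% names(df))
    as.character(df[[columnMap[["id"]]]][1L]) else "animal"
  trajectory(xs, ys, tsec, id = id)
}

.parseTimes <- function(tv, timeFormat, tz) {
  if (timeFormat == "auto")
    timeFormat <- if (is.numeric(tv)) "epoch" else "iso8601"
  if (timeFormat == "epoch") {
    num <- suppressWarnings(as.numeric(tv))
    bad <- which(is.na(num))
    if (length(bad))
      stop("unparseable numeric timestamp at data row ", bad[1L])
    return(num)
  }
  tv <- as.character(tv)
  parsed <- rep(NA_real_, length(tv))
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(parsed)
    if (!any(todo)) break
    p <- as.POSIXct(strptime(tv[todo], fmt, tz = tz))
    parsed[todo] <- as.numeric(p)
  }
  bad <- which(is.na(parsed))
  if (length(bad))
    stop("unparseable timestamp at data row ", bad[1L], ": '",
         tv[bad[1L]], "'")
  parsed
}

#' Resolve duplicate locations
#'
#' Fixes sharing an identical coordinate pair confound hull construction
#' (zero pairwise distances).  They can be left alone, deleted (keeping the
#' first in time), or randomly offset by a fixed amount in a uniformly
#' random direction.  Duplicate detection uses exact coordinate equality.
#'
#' @param traj a \code{\linkS4class{Trajectory}}.
#' @param mode "ignore", "delete" or "offset".
#' @param offsetDist displacement distance in map units (offset mode).
#' @param seed integer seed for the random offset directions.
#' @return A \code{\linkS4class{Trajectory}}.
#' @examples
#' tr <- trajectory(c(0, 0, 1), c(0, 0, 1), c(0, 10, 20))
#' nFixes(resolveDuplicates(tr, "delete"))
#' @export
resolveDuplicates <- function(traj, mode = c("ignore", "delete", "offset"),
                              offsetDist = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "ignore") return(traj)
  key <- paste(traj@coords[, 1L], traj@coords[, 2L], sep = "|")
  dup <- duplicated(key)
  if (!any(dup)) return(traj)
  if (mode == "delete") {
    return(new("Trajectory", coords = traj@coords[!dup, , drop = FALSE],
               time = traj@time[!dup], id = traj@id,
               rowIndex = traj@rowIndex[!dup]))
  }
  ## offset mode
  if (is.null(offsetDist) || !is.finite(offsetDist) || offsetDist <= 0)
    stop("mode = 'offset' requires a positive offsetDist")
  idx <- which(dup)
  ang <- withSeed(seed, stats::runif(length(idx), 0, 2 * pi))
  coords <- traj@coords
  coords[idx, 1L] <- coords[idx, 1L] + offsetDist * cos(ang)
  coords[idx, 2L] <- coords[idx, 2L] + offsetDist * sin(ang)
  new("Trajectory", coords = coords, time = traj@time, id = traj@id,
      rowIndex = traj@rowIndex)
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Per-fix speeds
#'
#' The speed of a fix sampled at time t is measured from t-1 to t+1: for an
#' interior fix the summed length of the two adjacent segments divided by
#' the total elapsed time; the first and last fix use their single adjacent
#' segment.  A zero elapsed time makes the speed undefined (\code{NA}).
#'
#' @param traj a \code{\linkS4class{Trajectory}} with n >= 2.
#' @return Numeric vector of speeds (map units / second), \code{NA} where
#'   undefined.
#' @examples
#' tr <- trajectory(c(0, 3, 6), c(0, 4, 8), c(0, 10, 20))
#' pointSpeeds(tr)   # all 0.5
#' @export
pointSpeeds <- function(traj) {
  n <- nFixes(traj)
  if (n < 2L) stop("need at least two fixes to compute speeds")
  xy <- traj@coords; tt <- traj@time
  segd <- sqrt(diff(xy[, 1L])^2 + diff(xy[, 2L])^2)   # length n-1
  sp <- numeric(n)
  den1 <- tt[2L] - tt[1L]
  sp[1L] <- if (den1 > 0) segd[1L] / den1 else NA_real_
  denN <- tt[n] - tt[n - 1L]
  sp[n] <- if (denN > 0) segd[n - 1L] / denN else NA_real_
  if (n > 2L) {
    i <- 2:(n - 1L)
    den <- tt[i + 1L] - tt[i - 1L]
    sp[i] <- ifelse(den > 0, (segd[i - 1L] + segd[i]) / den, NA_real_)
  }
  sp
}
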