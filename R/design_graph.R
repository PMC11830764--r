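# Ritual transition structure: two schemas (North/South), four paths (A-D),
# six rituals over the three analyzed stages (2, 3, 4). The intro (stage 1)
# and gift (stage 5) segments carry no analysis role and are not modeled.

.RITUAL_TABLE <- data.frame(
  name  = c("campfire", "flower", "coin", "torch", "egg", "painting"),
  stage = c(2L, 2L, 3L, 3L, 4L, 4L),
  stringsAsFactors = FALSE
)

.SCHEMAS <- c("North", "South")

.PATH_TABLE <- data.frame(
  id     = c("A", "B", "C", "D"),
  schema = c("North", "North", "South", "South"),
  stage2 = c("campfire", "flower", "campfire", "flower"),
  stage3 = c("coin", "torch", "torch", "coin"),
  stage4 = c("egg", "painting", "egg", "painting"),
  stringsAsFactors = FALSE
)

.check_schema <- function(schema) {
  if (!(is.character(schema) && length(schema) == 1L && schema %in% .SCHEMAS)) {
    stop("unknown schema: ", paste(schema, collapse = ", "),
         " (expected one of ", paste(.SCHEMAS, collapse = ", "), ")")
  }
  schema
}

#' Rituals of the wedding task
#'
#' @return A data frame with one row per ritual, columns `name` and `stage`.
#'   Stage 2 rituals are campfire and flower, stage 3 coin and torch,
#'   stage 4 egg and painting.
#' @export
rituals <- function() .RITUAL_TABLE

#' Schema labels
#'
#' @return Character vector `c("North", "South")`.
#' @export
schemas <- function() .SCHEMAS

#' Stage of a ritual
#'
#' @param ritual Ritual name.
#' @return Integer stage in 2:4.
#' @export
ritual_stage <- function(ritual) {
  i <- match(ritual, .RITUAL_TABLE$name)
  if (anyNA(i)) stop("unknown ritual: ", paste(ritual[is.na(i)], collapse = ", "))
  .RITUAL_TABLE$stage[i]
}

#' Enumerate the four ritual paths
#'
#' Each schema owns exactly two paths; the two paths of a schema are
#' disjoint at every stage, so (ritual, schema) identifies a unique path.
#'
#' @return Data frame with columns `id`, `schema`, `stage2`, `stage3`,
#'   `stage4`.
#' @export
enumerate_paths <- function() .PATH_TABLE

#' Ordered rituals of a path
#'
#' @param path_id One of "A", "B", "C", "D".
#' @return Character vector of the stage-2, stage-3 and stage-4 rituals.
#' @export
path_rituals <- function(path_id) {
  i <- match(path_id, .PATH_TABLE$id)
  if (is.na(i)) stop("unknown path: ", path_id)
  c(.PATH_TABLE$stage2[i], .PATH_TABLE$stage3[i], .PATH_TABLE$stage4[i])
}

#' Path containing a (ritual, schema) combination
#'
#' @param ritual Ritual name.
#' @param schema Schema label.
#' @return Path id ("A".."D").
#' @export
path_of <- function(ritual, schema) {
  st <- ritual_stage(ritual)
  .check_schema(schema)
  hit <- .PATH_TABLE$schema == schema &
    .PATH_TABLE[[paste0("stage", st)]] == ritual
  .PATH_TABLE$id[hit]
}

#' Next ritual under a schema
#'
#' The transition structure is non-Markovian: the successor of a stage-2 or
#' stage-3 ritual depends on the schema, not on the ritual alone (under
#' North, campfire is followed by coin; under South, by torch).
#'
#' @param schema Schema label.
#' @param current Ritual name, or `"START"` for the beginning of a wedding.
#' @return The successor ritual; `"UNPREDICTABLE"` for `"START"` (the two
#'   stage-2 rituals are equiprobable); `"END"` after a stage-4 ritual.
#' @export
next_ritual <- function(schema, current) {
  schema <- .check_schema(schema)
  if (identical(current, "START")) return("UNPREDICTABLE")
  st <- ritual_stage(current)
  if (st == 4L) return("END")
  hit <- .PATH_TABLE$schema == schema &
    .PATH_TABLE[[paste0("stage", st)]] == current
  .PATH_TABLE[[paste0("stage", st + 1L)]][hit]
}

#' Deduce the full path from schema plus stage-2 ritual
#'
#' @param schema Schema label.
#' @param stage2 A stage-2 ritual (campfire or flower).
#' @return One-row data frame (the matching row of [enumerate_paths()]).
#' @export
deduce_path <- function(schema, stage2) {
  .check_schema(schema)
  if (ritual_stage(stage2) != 2L) {
    stop("'", stage2, "' is not a stage-2 ritual")
  }
  .PATH_TABLE[.PATH_TABLE$schema == schema & .PATH_TABLE$stage2 == stage2, ]
}

#' Build a wedding schedule
#'
#' Day 2 is the analyzed session: 12 weddings, schemas in the fixed
#' interleaved order S,N,N,S,S,N,N,S,S,N,N,S, with the two paths of each
#' schema balanced 3/3 and their order randomized under `seed`. Day 1 is
#' the learning session: 24 weddings in four blocks of six (two blocks of
#' `first_context`, then two of the other schema), paths balanced 3/3
#' within each block.
#'
#' @param day 1 or 2.
#' @param first_context Schema shown first on day 1 (ignored for day 2).
#' @param seed Integer seed controlling path order.
#' @return A `wedding_schedule` data frame with columns `wedding_id`,
#'   `day`, `position`, `schema`, `path`, `ritual_stage2..4`.
#' @export
make_schedule <- function(day, first_context = "North", seed = 1L) {
  day <- as.integer(day)
  if (!day %in% c(1L, 2L)) stop("day must be 1 or 2")
  first_context <- .check_schema(first_context)
  set.seed(as.integer(seed))
  if (day == 2L) {
    schema <- ifelse(strsplit("SNNSSNNSSNNS", "")[[1]] == "S", "South", "North")
    path <- character(12L)
    for (s in .SCHEMAS) {
      ids <- .PATH_TABLE$id[.PATH_TABLE$schema == s]
      path[schema == s] <- sample(rep(ids, 3L))
    }
  } else {
    other <- setdiff(.SCHEMAS, first_context)
    schema <- rep(c(first_context, other), each = 12L)
    path <- character(24L)
    for (b in 0:3) {
      i <- b * 6L + 1:6
      ids <- .PATH_TABLE$id[.PATH_TABLE$schema == schema[i[1L]]]
      path[i] <- sample(rep(ids, 3L))
    }
  }
  n <- length(schema)
  out <- data.frame(
    wedding_id = seq_len(n), day = day, position = seq_len(n),
    schema = schema, path = path, stringsAsFactors = FALSE
  )
  pr <- .PATH_TABLE[match(out$path, .PATH_TABLE$id), ]
  out$ritual_stage2 <- pr$stage2
  out$ritual_stage3 <- pr$stage3
  out$ritual_stage4 <- pr$stage4
  class(out) <- c("wedding_schedule", "data.frame")
  out
}

#' Answer key for the end-of-study schema test
#'
#' One question per schema x cue ritual (campfire, flower, coin, torch):
#' "a couple from <schema> just performed <cue>; what happens next?".
#' The correct option is the successor under the cued schema; the
#' "opposite" option is the successor under the other schema.
#'
#' @return Data frame with 8 rows and columns `schema`, `cue_ritual`,
#'   `correct_next`, `opposite_next`.
#' @export
schema_test_key <- function() {
  cues <- c("campfire", "flower", "coin", "torch")
  out <- expand.grid(cue_ritual = cues, schema = .SCHEMAS,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("schema", "cue_ritual")]
  out$correct_next <- mapply(next_ritual, out$schema, out$cue_ritual)
  other <- ifelse(out$schema == "North", "South", "North")
  out$opposite_next <- mapply(next_ritual, other, out$cue_ritual)
  rownames(out) <- NULL
  out
}

#' Volume-level design of a schedule
#'
#' Expands a schedule to one row per acquired pattern, wedding-major and
#' stage-minor (the volume ordering contract used throughout the package).
#'
#' @param schedule A `wedding_schedule`.
#' @return Data frame with columns `volume`, `wedding_id`, `stage`,
#'   `schema`, `path`, `ritual`.
#' @export
volume_design <- function(schedule) {
  n <- nrow(schedule)
  df <- data.frame(
    volume = seq_len(3L * n),
    wedding_id = rep(schedule$wedding_id, each = 3L),
    stage = rep(2:4, n),
    schema = rep(schedule$schema, each = 3L),
    path = rep(schedule$path, each = 3L),
    stringsAsFactors = FALSE
  )
  rit <- rbind(schedule$ritual_stage2, schedule$ritual_stage3,
               schedule$ritual_stage4)
  df$ritual <- as.vector(rit)
  df
}

#' @export
print.wedding_schedule <- function(x, ...) {
  cat("wedding schedule: day", x$day[1L], "-", nrow(x), "weddings\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Write / read a schedule as TSV
#'
#' @param schedule A `wedding_schedule`.
#' @param path File path.
#' @return `read_schedule_tsv` returns a `wedding_schedule`.
#' @export
write_schedule_tsv <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_tsv
#' @export
read_schedule_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("wedding_id", "day", "position", "schema", "path",
            "ritual_stage2", "ritual_stage3", "ritual_stage4")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("schedule TSV missing columns: ",
                         paste(miss, collapse = ", "))
  class(out) <- c("wedding_schedule", "data.frame")
  out
}
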