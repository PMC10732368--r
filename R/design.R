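#' Speed classes of the reaching task
#'
#' Each reach is a slow, medium or fast movement: 15, 20 or 25 cm covered in
#' the same nominal movement time, so desired peak speeds are 45, 60 and
#' 75 cm/s with a compliance band of +/-10% of the desired peak.
#'
#' @return A tibble with one row per speed class and columns `class`,
#'   `distance_cm`, `peak_speed_cm_s`, `tolerance_cm_s` and
#'   `movement_time_ms` (the nominal instructed movement time).
#' @export
#' @examples
#' speed_classes()
speed_classes <- function() {
  tibble::tibble(
    class = c("slow", "medium", "fast"),
    distance_cm = c(15, 20, 25),
    peak_speed_cm_s = c(45, 60, 75),
    tolerance_cm_s = c(4.5, 6, 7.5),
    movement_time_ms = 700
  )
}

speed_class_row <- function(class) {
  sc <- speed_classes()
  row <- sc[sc$class == class, ]
  if (nrow(row) != 1L) {
    abort(paste0("unknown speed class '", class, "'"),
          class = "curladapt_invalid_parameter")
  }
  row
}

#' Enumerate the twelve task conditions
#'
#' The condition grid crosses the three left-hand speed classes with the
#' three right-hand speed classes (nine bimanual conditions, labelled
#' `b_<left><right>`, e.g. `b_sf` = slow left, fast right) and adds the three
#' unimanual conditions in which only the left hand moves (`u_s`, `u_m`,
#' `u_f`; the right hand is stationary).
#'
#' Ordering is deterministic: bimanual conditions row-major by left then
#' right class (slow, medium, fast), followed by the unimanual conditions
#' slow to fast.
#'
#' @return A tibble with columns `label`, `left_class`, `right_class`
#'   (`"none"` for unimanual conditions) and `bimanual` (logical).
#' @export
#' @examples
#' condition_grid()
condition_grid <- function() {
  cls <- c("slow", "medium", "fast")
  code <- c(slow = "s", medium = "m", fast = "f")
  bi <- tidyr::expand_grid(left_class = cls, right_class = cls)
  bi$label <- paste0("b_", code[bi$left_class], code[bi$right_class])
  uni <- tibble::tibble(
    left_class = cls,
    right_class = "none",
    label = paste0("u_", code[cls])
  )
  out <- dplyr::bind_rows(bi, uni)
  out$bimanual <- out$right_class != "none"
  out[, c("label", "left_class", "right_class", "bimanual")]
}

#' Training-group designs
#'
#' The evident group trains on conditions in which the two hands move at
#' different speeds (`b_sf`, `b_mm`, `b_fs`), exposing the dependence of the
#' left-hand force field on right-hand velocity. The ambiguous group trains
#' on matched-speed conditions (`b_ff`, `b_mm`, `b_ss`), which hide it.
#'
#' @param group `"evident"` or `"ambiguous"`.
#' @return A list with elements `group` and `trained_conditions`
#'   (a character vector of three bimanual condition labels).
#' @export
#' @examples
#' group_design("evident")$trained_conditions
group_design <- function(group = c("evident", "ambiguous")) {
  if (!is.character(group) || length(group) < 1L ||
      !group[[1]] %in% c("evident", "ambiguous")) {
    abort("`group` must be \"evident\" or \"ambiguous\"",
          class = "curladapt_invalid_design")
  }
  group <- group[[1]]
  trained <- switch(group,
    evident = c("b_sf", "b_mm", "b_fs"),
    ambiguous = c("b_ff", "b_mm", "b_ss")
  )
  list(group = group, trained_conditions = trained)
}

block_tbl <- function(condition, field_type) {
  tibble::tibble(condition = condition, field_type = field_type)
}

#' Build the full three-phase trial schedule
#'
#' Constructs the complete 2208-trial design for one participant of either
#' group:
#'
#' * **baseline** (6 blocks of 48 null-field trials): blocks 1-5 present each
#'   of the 12 conditions three times in the null field plus once as an error
#'   clamp; block 6 presents only the group's three trained conditions, 14
#'   null + 2 clamp each.
#' * **exposure** (20 blocks of 48): per trained condition, 14 force-field
#'   trials and 2 error clamps.
#' * **generalization** (20 blocks of 48): 12 force-field trials per trained
#'   condition plus one error clamp for each of the 12 conditions.
#'
#' Trial order is randomized independently within every block by the seeded
#' generator; equal seeds give identical schedules. Unimanual trials never
#' receive the force field (none is ever applied when the right hand is
#' stationary) and no force field occurs in baseline. Consecutive clamp
#' trials are permitted (order within a block is a uniform shuffle).
#'
#' @param group `"evident"` or `"ambiguous"` (or a list from
#'   [group_design()]).
#' @param seed Non-negative integer seed for the within-block shuffles.
#' @return A tibble with columns `trial` (1-based), `phase`
#'   (baseline/exposure/generalization), `block` (1-based within phase),
#'   `condition` and `field_type` (null/force_field/clamp).
#' @export
#' @examples
#' sched <- build_schedule("evident", seed = 1)
#' dplyr::count(sched, phase)
build_schedule <- function(group = c("evident", "ambiguous"), seed = 1L) {
  gd <- if (is.list(group)) group else group_design(group)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0) {
    abort("`seed` must be a single non-negative integer",
          class = "curladapt_invalid_parameter")
  }
  conds <- condition_grid()$label
  trained <- gd$trained_conditions

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))

  shuffle <- function(tbl) tbl[sample.int(nrow(tbl)), ]

  baseline_std <- dplyr::bind_rows(
    block_tbl(rep(conds, times = 3), "null"),
    block_tbl(conds, "clamp")
  )
  baseline_last <- dplyr::bind_rows(
    block_tbl(rep(trained, times = 14), "null"),
    block_tbl(rep(trained, times = 2), "clamp")
  )
  exposure_block <- dplyr::bind_rows(
    block_tbl(rep(trained, times = 14), "force_field"),
    block_tbl(rep(trained, times = 2), "clamp")
  )
  general_block <- dplyr::bind_rows(
    block_tbl(rep(trained, times = 12), "force_field"),
    block_tbl(conds, "clamp")
  )

  phases <- list(
    baseline = c(rep(list(baseline_std), 5), list(baseline_last)),
    exposure = rep(list(exposure_block), 20),
    generalization = rep(list(general_block), 20)
  )

  out <- purrr::imap(phases, function(blocks, phase) {
    purrr::imap(blocks, function(tbl, b) {
      res <- shuffle(tbl)
      res$phase <- phase
      res$block <- b
      res
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  out$trial <- seq_len(nrow(out))
  tibble::as_tibble(out[, c("trial", "phase", "block", "condition", "field_type")])
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_set <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
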