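#' Experimental condition descriptor
#'
#' A block-level condition in the 2 x 2 (x distractor) design.
#' `background_symmetry` is block-level: symmetric blocks use one
#' uniform background (gray or blue) for both stimuli; asymmetric
#' blocks split the display into a gray field on the left and a blue
#' field on the right. `delay` distinguishes simultaneous presentation
#' from a 2 s retention interval (the reference is always shown in the
#' first interval of delay blocks). Distractor stimuli can only be
#' shown during a delay.
#'
#' @param background_symmetry One of `"symmetric_gray"`,
#'   `"symmetric_blue"`, `"asymmetric"`.
#' @param delay `"simultaneous"` or `"delay_2s"`.
#' @param distractors `"none"` or `"present"` (requires `delay_2s`).
#' @return A `condition` object.
#' @examples
#' condition("asymmetric", "delay_2s")
#' @export
condition <- function(background_symmetry = c("symmetric_gray", "symmetric_blue",
                                              "asymmetric"),
                      delay = c("simultaneous", "delay_2s"),
                      distractors = c("none", "present")) {
  background_symmetry <- match.arg(background_symmetry)
  delay <- match.arg(delay)
  distractors <- match.arg(distractors)
  if (distractors == "present" && delay != "delay_2s")
    stop("distractors require a delay condition")
  structure(list(background_symmetry = background_symmetry,
                 delay = delay, distractors = distractors),
            class = "exp_condition")
}

#' @export
print.exp_condition <- function(x, ...) {
  cat(sprintf("condition: %s / %s / distractors %s\n",
              x$background_symmetry, x$delay, x$distractors))
  invisible(x)
}

# Canonical names of the four main conditions plus distractor variants.
condition_names <- function() {
  c("baseline", "constancy", "memory", "joint",
    "memory_distractor", "joint_distractor")
}

#' Expand a named condition into its blocks
#'
#' The factorial conditions are blocked: symmetric conditions
#' (baseline, memory) comprise one uniform-gray and one uniform-blue
#' block, so both reference backgrounds are measured; asymmetric
#' conditions (constancy, joint) are a single block in which both
#' reference-background assignments are interleaved.
#'
#' @param name One of `"baseline"`, `"constancy"`, `"memory"`,
#'   `"joint"`, `"memory_distractor"`, `"joint_distractor"`.
#' @return A list of [condition()] objects, one per block.
#' @export
condition_blocks <- function(name) {
  name <- match.arg(name, condition_names())
  delay <- if (name %in% c("baseline", "constancy")) "simultaneous" else "delay_2s"
  distr <- if (grepl("_distractor$", name)) "present" else "none"
  if (name %in% c("constancy", "joint", "joint_distractor")) {
    list(condition("asymmetric", delay, distr))
  } else {
    list(condition("symmetric_gray", delay, distr),
         condition("symmetric_blue", delay, distr))
  }
}

# Background of the reference / test patch given a block condition and
# the reference-background assignment of the trial. In asymmetric
# blocks the gray field is on the left and the blue field on the
# right, so the side is determined by the background; in symmetric
# blocks both patches share the block background.
reference_background_set <- function(cond) {
  switch(cond$background_symmetry,
         symmetric_gray = "gray",
         symmetric_blue = "blue",
         asymmetric = c("gray", "blue"))
}

other_background <- function(bg) ifelse(bg == "gray", "blue", "gray")

test_background_for <- function(cond, reference_background) {
  if (cond$background_symmetry == "asymmetric")
    other_background(reference_background)
  else
    reference_background
}

# Side of the reference patch. Asymmetric blocks pin gray to the left
# and blue to the right; symmetric blocks randomize the side.
reference_side_for <- function(cond, reference_background, n = length(reference_background)) {
  if (cond$background_symmetry == "asymmetric") {
    ifelse(reference_background == "gray", "left", "right")
  } else {
    sample(c("left", "right"), n, replace = TRUE)
  }
}
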