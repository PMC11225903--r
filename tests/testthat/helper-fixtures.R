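# shared in-code fixtures

POACHER_SENTENCE <- paste("Five poachers were arrested on June 10, 2019",
                          "and sentenced to prison on August 8, 2019.")

# minimal hand-built taxonomy around the arrest/sentence vocabulary
arrest_taxonomy <- function() {
  emat_taxonomy(
    action_id = c(1L, 2L),
    category = c("militaristic", "militaristic"),
    label = c("arrest poachers", "sentence offenders"),
    actors = list("rangers", "courts"),
    verbs = list(c("arrest", "arrested"), c("sentenced", "convicted")),
    objects = list(c("poachers", "five poachers"), c("offenders")),
    preps = list(c("in the park"), c("to prison"))
  )
}

write_tmp_lines <- function(lines) {
  p <- withr::local_tempfile(.local_envir = parent.frame(), fileext = ".txt")
  writeLines(lines, p)
  p
}
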