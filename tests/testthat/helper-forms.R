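# the 24 cluster sequences of the published form table, frozen for tests
expected_forms <- function() {
  txt <- "READ1 READ2 MATH1 MATH2
READ2 READ1 MATH2 MATH1
READ1 READ2 MATH2 MATH1
READ2 READ1 MATH1 MATH2
MATH1 MATH2 READ1 READ2
MATH2 MATH1 READ2 READ1
MATH1 MATH2 READ2 READ1
MATH2 MATH1 READ1 READ2
SCIE1 SCIE2 READ1 READ2
SCIE2 SCIE1 READ2 READ1
SCIE1 SCIE2 READ2 READ1
SCIE2 SCIE1 READ1 READ2
READ1 READ2 SCIE1 SCIE2
READ2 READ1 SCIE2 SCIE1
READ1 READ2 SCIE2 SCIE1
READ2 READ1 SCIE1 SCIE2
MATH1 MATH2 SCIE1 SCIE2
MATH2 MATH1 SCIE2 SCIE1
MATH1 MATH2 SCIE2 SCIE1
MATH2 MATH1 SCIE1 SCIE2
SCIE1 SCIE2 MATH1 MATH2
SCIE2 SCIE1 MATH2 MATH1
SCIE1 SCIE2 MATH2 MATH1
SCIE2 SCIE1 MATH1 MATH2"
  m <- do.call(rbind, strsplit(strsplit(txt, "\n")[[1]], " "))
  data.frame(form_id = 1:24, cluster1 = m[, 1], cluster2 = m[, 2],
             cluster3 = m[, 3], cluster4 = m[, 4],
             stringsAsFactors = FALSE)
}

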