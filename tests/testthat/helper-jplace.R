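# hand-built 5-tip jplace fixture (version 3)
jplace_text <- function() {
  paste0('{"version": 3,',
         '"tree": "((A:0.1{0},B:0.2{1}):0.05{5},(C:0.3{2},(D:0.4{3},E:0.5{4}):0.02{6}):0.06{7});",',
         '"fields": ["edge_num", "like_weight_ratio", "pendant_length", "distal_length"],',
         '"placements": [',
         '{"p": [[0, 0.6, 0.01, 0.05], [2, 0.35, 0.02, 0.0], [6, 0.2, 0.03, 0.0]], "n": ["q1"]},',
         '{"p": [[3, 1.0, 0.0, 0.1]], "nm": [["q2", 5]]}',
         '],',
         '"metadata": {"invocation": "fixture"}}')
}

local_jplace <- function(env = parent.frame()) {
  tmp <- withr::local_tempfile(fileext = ".jplace", .local_envir = env)
  writeLines(jplace_text(), tmp)
  tmp
}

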