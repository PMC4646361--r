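graph [
  comment "Zachary karate club social network"
  directed 0
  node [
    id 0
    label "v1"
  ]
  node [
    id 1
    label "v2"
  ]
  node [
    id 2
    label "v3"
  ]
  node [
    id 3
    label "v4"
  ]
  node [
    id 4
    label "v5"
  ]
  node [
    id 5
    label "v6"
  ]
  node [
    id 6
    label "v7"
  ]
  node [
    id 7
    label "v8"
  ]
  node [
    id 8
    label "v9"
  ]
  node [
    id 9
    label "v10"
  ]
  node [
    id 10
    label "v11"
  ]
  node [
    id 11
    label "v12"
  ]
  node [
    id 12
    label "v13"
  ]
  node [
    id 13
    label "v14"
  ]
  node [
    id 14
    label "v15"
  ]
  node [
    id 15
    label "v16"
  ]
  node [
    id 16
    label "v17"
  ]
  node [
    id 17
    label "v18"
  ]
  node [
    id 18
    label "v19"
  ]
  node [
    id 19
    label "v20"
  ]
  node [
    id 20
    label "v21"
  ]
  node [
    id 21
    label "v22"
  ]
  node [
    id 22
    label "v23"
  ]
  node [
    id 23
    label "v24"
  ]
  node [
    id 24
    label "v25"
  ]
  node [
    id 25
    label "v26"
  ]
  node [
    id 26
    label "v27"
  ]
  node [
    id 27
    label "v28"
  ]
  node [
    id 28
    label "v29"
  ]
  node [
    id 29
    label "v30"
  ]
  node [
    id 30
    label "v31"
  ]
  node [
    id 31
    label "v32"
  ]
  node [
    id 32
    label "v33"
  ]
  node [
    id 33
    label "v34"
  ]
  edge [
    source 0
    target 1
  ]
  edge [
    source 0
    target 2
  ]
  edge [
    source 0
    target 3
  ]
  edge [
    source 0
    target 4
  ]
  edge [
    source 0
    target 5
  ]
  edge [
    source 0
    target 6
  ]
  edge [
    source 0
    target 7
  ]
  edge [
    source 0
    target 8
  ]
  edge [
    source 0
    target 10
  ]
  edge [
    source 0
    target 11
  ]
  edge [
    source 0
    target 12
  ]
  edge [
    source 0
    target 13
  ]
  edge [
    source 0
    target 17
  ]
  edge [
    source 0
    target 19
  ]
  edge [
    source 0
    target 21
  ]
  edge [
    source 0
    target 31
  ]
  edge [
    source 1
    target 2
  ]
  edge [
    source 1
    target 3
  ]
  edge [
    source 1
    target 7
  ]
  edge [
    source 1
    target 13
  ]
  edge [
    source 1
    target 17
  ]
  edge [
    source 1
    target 19
  ]
  edge [
    source 1
    target 21
  ]
  edge [
    source 1
    target 30
  ]
  edge [
    source 2
    target 3
  ]
  edge [
    source 2
    target 7
  ]
  edge [
    source 2
    target 27
  ]
  edge [
    source 2
    target 28
  ]
  edge [
    source 2
    target 32
  ]
  edge [
    source 2
    target 9
  ]
  edge [
    source 2
    target 8
  ]
  edge [
    source 2
    target 13
  ]
  edge [
    source 3
    target 7
  ]
  edge [
    source 3
    target 12
  ]
  edge [
    source 3
    target 13
  ]
  edge [
    source 4
    target 6
  ]
  edge [
    source 4
    target 10
  ]
  edge [
    source 5
    target 6
  ]
  edge [
    source 5
    target 10
  ]
  edge [
    source 5
    target 16
  ]
  edge [
    source 6
    target 16
  ]
  edge [
    source 8
    target 30
  ]
  edge [
    source 8
    target 32
  ]
  edge [
    source 8
    target 33
  ]
  edge [
    source 9
    target 33
  ]
  edge [
    source 13
    target 33
  ]
  edge [
    source 14
    target 32
  ]
  edge [
    source 14
    target 33
  ]
  edge [
    source 15
    target 32
  ]
  edge [
    source 15
    target 33
  ]
  edge [
    source 18
    target 32
  ]
  edge [
    source 18
    target 33
  ]
  edge [
    source 19
    target 33
  ]
  edge [
    source 20
    target 32
  ]
  edge [
    source 20
    target 33
  ]
  edge [
    source 22
    target 32
  ]
  edge [
    source 22
    target 33
  ]
  edge [
    source 23
    target 25
  ]
  edge [
    source 23
    target 27
  ]
  edge [
    source 23
    target 32
  ]
  edge [
    source 23
    target 33
  ]
  edge [
    source 23
    target 29
  ]
  edge [
    source 24
    target 25
  ]
  edge [
    source 24
    target 27
  ]
  edge [
    source 24
    target 31
  ]
  edge [
    source 25
    target 31
  ]
  edge [
    source 26
    target 29
  ]
  edge [
    source 26
    target 33
  ]
  edge [
    source 27
    target 33
  ]
  edge [
    source 28
    target 31
  ]
  edge [
    source 28
    target 33
  ]
  edge [
    source 29
    target 32
  ]
  edge [
    source 29
    target 33
  ]
  edge [
    source 30
    target 32
  ]
  edge [
    source 30
    target 33
  ]
  edge [
    source 31
    target 32
  ]
  edge [
    source 31
    target 33
  ]
  edge [
    source 32
    target 33
  ]
]
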