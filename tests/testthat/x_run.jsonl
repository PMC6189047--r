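{"time":"2026-09-20T14:45:40","event":"start","subcommand":"simulate","seed":1} 
{"time":"2026-09-20T14:46:25","event":"start","subcommand":"simulate","seed":1} 
{"time":"2026-09-20T14:47:04","event":"start","subcommand":"simulate","seed":1} 
{"time":"2026-09-20T14:49:57","event":"start","subcommand":"simulate","seed":1} 
{"time":"2026-09-20T14:53:07","event":"start","subcommand":"simulate","seed":1} 
{"time":"2026-09-20T15:03:34","event":"start","subcommand":"simulate","seed":1} 
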