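{"subcommand":"train","seed":1,"outDir":".","logLevel":"info","input":"/nonexistent/file.tsv","kind":"matched","epochs":100,"topFrac":0.2,"bottomFrac":0.2,"modelOut":"model.rds"}
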