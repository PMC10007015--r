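aorta abdominal aneurysm	false
aortic aneurysm abdominal	false
aneurysm abdominal aorta	false
infrarenal aortic aneurysm	false
AAA	true
AAAs	true
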