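<?xml version="1.0" encoding="UTF-8"?>
<aiml version="subset-1" language="es">
  <category>
    <pattern>gracias</pattern>
    <template><random><li>De nada. ¿Seguimos platicando?</li><li>Con mucho gusto. ¿De qué más te gustaría hablar?</li></random></template>
  </category>
  <category>
    <pattern>gracias *</pattern>
    <template><srai>gracias</srai></template>
  </category>
  <category>
    <pattern>* gracias</pattern>
    <template><srai>gracias</srai></template>
  </category>
</aiml>
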