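<?xml version="1.0" encoding="UTF-8"?>
<aiml version="subset-1" language="es">
<topic name="pwad_profile" description="the patient's own personal information">
  <category trigger="true" entry="true">
    <pattern>vida</pattern>
    <template><random><li>¿Es verdad que te dicen <get name="apodo"/>?</li><li>¿Te gustaría platicar de cuando vivías en <get name="lugar_nacimiento"/>?</li><li>¿Me cuentas algo de tu vida?</li></random></template>
  </category>
  <category trigger="true">
    <pattern>vida *</pattern>
    <template><srai>vida</srai></template>
  </category>
  <category trigger="true">
    <pattern>* vida</pattern>
    <template><srai>vida</srai></template>
  </category>
  <category trigger="true">
    <pattern>* vida *</pattern>
    <template><srai>vida</srai></template>
  </category>
  <category>
    <pattern>sí</pattern>
    <template><random><li>¡Qué bien! ¿Qué recuerdas de <get name="lugar_nacimiento"/>?</li><li>¡Muy bien! ¿Me cuentas un recuerdo bonito de tu vida?</li></random></template>
  </category>
  <category>
    <pattern>sí *</pattern>
    <template><srai>sí</srai></template>
  </category>
  <category>
    <pattern>* sí</pattern>
    <template><srai>sí</srai></template>
  </category>
  <category>
    <pattern>si</pattern>
    <template><srai>sí</srai></template>
  </category>
  <category>
    <pattern>si *</pattern>
    <template><srai>sí</srai></template>
  </category>
  <category>
    <pattern>* si</pattern>
    <template><srai>sí</srai></template>
  </category>
  <category>
    <pattern>no</pattern>
    <template><random><li>Está bien. ¿De qué otra cosa te gustaría platicar?</li><li>No hay problema. ¿Hay otro tema que te guste más?</li></random></template>
  </category>
  <category>
    <pattern>no *</pattern>
    <template><srai>no</srai></template>
  </category>
  <category fallback="true">
    <pattern>fallback</pattern>
    <template><random><li>Entiendo. ¿Me cuentas un poco más?</li><li>Ya veo. ¿Qué más recuerdas de eso?</li></random></template>
  </category>
</topic>
</aiml>
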